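.pkg_cache <- new.env(parent = emptyenv())

#' Generate a BRIEF-style binary test pattern
#'
#' Draws `n_pairs` ordered pixel-pair offsets inside a
#' `(2 * patch_radius + 1)^2` patch, each coordinate sampled from a Gaussian
#' of standard deviation `sigma`, rounded and clipped to the patch. Pairs
#' whose two endpoints coincide are redrawn, since such a test is always 0.
#' Descriptors are only comparable when computed under the same pattern; the
#' package ships one frozen pattern (see [brief_pattern()]) and this
#' generator exists to reproduce or replace it deliberately.
#'
#' @param seed RNG seed; `seed = 42` reproduces the shipped pattern.
#' @param n_pairs number of binary tests (descriptor length in bits).
#' @param patch_radius half-width of the square patch.
#' @param sigma Gaussian spread of sampled offsets, in pixels.
#' @return Integer matrix with `n_pairs` rows and columns `x1, y1, x2, y2`.
#' @export
generate_brief_pattern <- function(seed = 42, n_pairs = 256,
                                   patch_radius = 15, sigma = 31 / 5) {
  with_seed_local(seed, {
    draw <- function(n) {
      v <- round(rnorm(n, 0, sigma))
      pmin(pmax(v, -patch_radius), patch_radius)
    }
    pat <- matrix(0L, n_pairs, 4,
                  dimnames = list(NULL, c("x1", "y1", "x2", "y2")))
    i <- 1L
    while (i <= n_pairs) {
      p <- as.integer(draw(4))
      if (p[1] == p[3] && p[2] == p[4]) next
      pat[i, ] <- p
      i <- i + 1L
    }
    pat
  })
}

#' The shipped descriptor test pattern
#'
#' Reads (and caches) the frozen 256-pair test pattern distributed with the
#' package as a plain-text table. All descriptors computed by this package
#' default to this pattern.
#'
#' @return Integer matrix of 256 rows and columns `x1, y1, x2, y2`.
#' @export
brief_pattern <- function() {
  if (!is.null(.pkg_cache$pattern)) return(.pkg_cache$pattern)
  path <- system.file("extdata", "brief_pattern.tsv", package = "aomontage",
                      mustWork = TRUE)
  tab <- read.delim(path, sep = "\t")
  pat <- as.matrix(tab)
  storage.mode(pat) <- "integer"
  colnames(pat) <- c("x1", "y1", "x2", "y2")
  .pkg_cache$pattern <- pat
  pat
}

validate_pattern <- function(pattern, patch_radius = 15) {
  stopifnot(is.matrix(pattern), ncol(pattern) == 4)
  if (any(abs(pattern) > patch_radius))
    stop("pattern offsets must lie within [-", patch_radius, ", ",
         patch_radius, "]", call. = FALSE)
  storage.mode(pattern) <- "integer"
  pattern
}
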