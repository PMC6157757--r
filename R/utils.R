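#' @useDynLib aomontage, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd cor setNames
#' @importFrom utils read.csv write.csv read.delim
#' @importFrom tools file_ext
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed_local <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation, kept inside 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647)
}

# Validate an 8-bit grayscale image matrix (rows = y, cols = x).
assert_gray_image <- function(img, min_side = NULL, what = "image") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop(what, " intensities must be in [0, 255]", call. = FALSE)
  if (!is.null(min_side) && (nrow(img) < min_side || ncol(img) < min_side))
    stop("image too small: need at least ", min_side, "x", min_side,
         " pixels", call. = FALSE)
  invisible(img)
}

MODALITIES <- c("confocal", "split", "dark")
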