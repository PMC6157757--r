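#' Extract the overlap region of two tiles under a translation
#'
#' Rounds the translation to the pixel grid and returns the two tiles'
#' intensities over their common region in the destination frame.
#'
#' @param imgA,imgB image matrices (source and destination).
#' @param t numeric `c(tx, ty)`: maps A pixel coordinates into B's frame.
#' @return `NULL` if the overlap is empty, else list of equally shaped
#'   matrices `A` and `B`.
#' @export
overlap_region <- function(imgA, imgB, t) {
  rx <- round(t[1]); ry <- round(t[2])
  # B-frame overlap box (0-based)
  x0 <- max(0, rx); x1 <- min(ncol(imgB), ncol(imgA) + rx)
  y0 <- max(0, ry); y1 <- min(nrow(imgB), nrow(imgA) + ry)
  if (x1 <= x0 || y1 <= y0) return(NULL)
  B <- imgB[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
  A <- imgA[(y0 - ry + 1):(y1 - ry), (x0 - rx + 1):(x1 - rx), drop = FALSE]
  list(A = A, B = B)
}

#' Normalised cross correlation of an overlap region
#'
#' Pearson correlation of the two intensity arrays (zero-mean,
#' unit-variance normalisation); in `[-1, 1]`.
#'
#' @param region list with matrices `A` and `B` of equal shape.
#' @return NCC score.
#' @export
ncc <- function(region) {
  a <- as.numeric(region$A); b <- as.numeric(region$B)
  stopifnot(length(a) == length(b), length(a) >= 2)
  if (sd(a) == 0 || sd(b) == 0)
    stop("undefined NCC: constant intensity array", call. = FALSE)
  cor(a, b)
}

#' Normalised mutual information of an overlap region
#'
#' `2 I(A; B) / (H(A) + H(B))` from a joint histogram of `bins` equal-width
#' bins per axis over `[0, 255]`; bounded in `[0, 1]`. A degenerate
#' (single-occupied-bin) marginal yields 0 by convention.
#'
#' @param region list with matrices `A` and `B` of equal shape.
#' @param bins histogram bins per axis.
#' @return NMI score.
#' @export
nmi <- function(region, bins = 32) {
  a <- as.numeric(region$A); b <- as.numeric(region$B)
  stopifnot(length(a) == length(b), length(a) >= bins)
  cut_idx <- function(v) pmin(floor(v / 256 * bins), bins - 1) + 1
  ia <- cut_idx(a); ib <- cut_idx(b)
  joint <- table(factor(ia, levels = 1:bins), factor(ib, levels = 1:bins))
  p <- joint / sum(joint)
  pa <- rowSums(p); pb <- colSums(p)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  ha <- ent(pa); hb <- ent(pb)
  if (ha == 0 || hb == 0) return(0)
  pnz <- p[p > 0]
  hab <- -sum(pnz * log(pnz))
  mi <- ha + hb - hab
  2 * mi / (ha + hb)
}

#' Score a completed montage
#'
#' Computes NCC and NMI over the overlap region of every accepted pairwise
#' edge (under its accepted transform) and reports their means along with
#' the number of disjoint components. Edges with empty or constant overlap
#' are skipped with a warning.
#'
#' @param tiles list of tiles (or [prepare_tiles()] output).
#' @param result a `montage_result`.
#' @param modality modality to score on.
#' @param bins NMI histogram bins.
#' @return List with `mean_ncc`, `mean_nmi` (both `NA` if there are no
#'   edges) and `pieces`.
#' @export
evaluate_montage <- function(tiles, result, modality = "confocal",
                             bins = 32) {
  get_img <- function(id) {
    t <- tiles[[id]]
    t <- if (!is.null(t$features)) t$tile else t
    t$modalities[[modality]]
  }
  edges <- result$pairwise
  nccs <- numeric(0); nmis <- numeric(0)
  if (nrow(edges) > 0) {
    for (i in seq_len(nrow(edges))) {
      reg <- overlap_region(get_img(edges$src[i]), get_img(edges$dst[i]),
                            c(edges$tx[i], edges$ty[i]))
      if (is.null(reg)) {
        warning("edge ", edges$src[i], " -> ", edges$dst[i],
                " has zero-area overlap; skipped")
        next
      }
      if (sd(as.numeric(reg$A)) == 0 || sd(as.numeric(reg$B)) == 0) {
        warning("edge ", edges$src[i], " -> ", edges$dst[i],
                " has constant overlap; skipped")
        next
      }
      nccs <- c(nccs, ncc(reg))
      nmis <- c(nmis, nmi(reg, bins))
    }
  }
  list(mean_ncc = if (length(nccs)) mean(nccs) else NA_real_,
       mean_nmi = if (length(nmis)) mean(nmis) else NA_real_,
       pieces = length(result$components))
}

#' Overlap required to match a tile pair
#'
#' Reproduces the overlap-requirement experiment: one tile of a pair with
#' known ground-truth translation is cropped on the side facing the other
#' so that the true overlap equals each requested width, the pair is then
#' matched and aligned, and a trial succeeds when the alignment is accepted
#' (consensus inliers exceeding `T2`) and its translation is within
#' `success_tol` pixels of the truth. Trials at a given width differ in the
#' LSH bit-sampling seed (the stochastic element of the matcher).
#'
#' @param tileA,tileB tiles (named modality lists with images).
#' @param truth numeric `c(tx, ty)`: ground-truth translation mapping A
#'   pixels into B's frame.
#' @param overlaps overlap widths to test, in pixels.
#' @param trials trials per width.
#' @param seed base seed.
#' @param params a [montage_params()] object (supplies `T2`).
#' @param detector,matcher,ransac,pattern pipeline parameters.
#' @param success_tol success tolerance in pixels (Euclidean).
#' @return Data frame: `overlap_px`, `n_trials`, `n_success`, `proportion`.
#' @export
overlap_sweep <- function(tileA, tileB, truth, overlaps, trials = 3,
                          seed = 0, params = montage_params(),
                          detector = detector_params(),
                          matcher = matcher_params(),
                          ransac = ransac_params(),
                          pattern = brief_pattern(),
                          success_tol = 2) {
  axis <- if (abs(truth[1]) >= abs(truth[2])) "x" else "y"
  wA <- if (axis == "x") ncol(tileA$modalities[[1]])
        else nrow(tileA$modalities[[1]])
  wB <- if (axis == "x") ncol(tileB$modalities[[1]])
        else nrow(tileB$modalities[[1]])
  # true overlap along the facing axis (A maps into B by `truth`)
  off <- truth[if (axis == "x") 1 else 2]
  full <- if (off <= 0) min(wA + off, wB) else min(wB - off, wA)
  if (max(overlaps) > full)
    stop("requested overlap exceeds the pair's true overlap (", full,
         " px)", call. = FALSE)
  featB <- lapply(tileB$modalities, function(img)
    detect_and_describe(img, detector, pattern))
  out <- data.frame(overlap_px = overlaps, n_trials = trials,
                    n_success = 0L, proportion = 0)
  for (wi in seq_along(overlaps)) {
    w <- overlaps[wi]
    crop <- crop_to_overlap(tileA, truth, axis, full, w)
    featA <- lapply(crop$tile$modalities, function(img)
      detect_and_describe(img, detector, pattern))
    featA <- Filter(function(f) ncol(f$descriptors) > 0, featA)
    n_succ <- 0L
    for (k in seq_len(trials)) {
      est <- tryCatch({
        m <- match_tiles(featA, featB, matcher,
                         lsh_seed = derive_seed(seed, wi * 1000 + k))
        ransac_align(m, ransac)
      }, error = function(e) NULL)
      if (is.null(est) || est$consensus_count <= params$T2) next
      err <- sqrt((est$tx - crop$truth[1])^2 + (est$ty - crop$truth[2])^2)
      if (err <= success_tol) n_succ <- n_succ + 1L
    }
    out$n_success[wi] <- n_succ
    out$proportion[wi] <- n_succ / trials
  }
  out
}

# Crop tile A on the side facing B so the true overlap equals `w` pixels.
# Cropping the leading (left/top) side shifts A's pixel frame, so the truth
# translation is adjusted by the number of removed pixels.
crop_to_overlap <- function(tileA, truth, axis, full, w) {
  remove <- full - w
  t2 <- truth
  mods <- tileA$modalities
  if (remove > 0) {
    if (axis == "x") {
      if (truth[1] <= 0) {            # B lies to the right: crop A's right
        mods <- lapply(mods, function(im) im[, 1:(ncol(im) - remove),
                                             drop = FALSE])
      } else {                        # B to the left: crop A's left
        mods <- lapply(mods, function(im) im[, (remove + 1):ncol(im),
                                             drop = FALSE])
        t2[1] <- truth[1] + remove
      }
    } else {
      if (truth[2] <= 0) {
        mods <- lapply(mods, function(im) im[1:(nrow(im) - remove), ,
                                             drop = FALSE])
      } else {
        mods <- lapply(mods, function(im) im[(remove + 1):nrow(im), ,
                                             drop = FALSE])
        t2[2] <- truth[2] + remove
      }
    }
  }
  tile <- tileA
  tile$modalities <- mods
  list(tile = tile, truth = t2)
}
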