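#' Build a Gaussian image pyramid
#'
#' Level 0 is the input image; level `k` has dimensions
#' `floor(dim / scale_factor^k)`. Each level is Gaussian-smoothed before
#' decimation (bilinear resampling), so coarse levels are alias-free.
#' Levels whose smaller side would fall below 31 px (the descriptor patch)
#' are dropped.
#'
#' @param image numeric matrix of 8-bit intensities, rows = y, cols = x.
#' @param scale_factor per-level downsampling ratio (> 1).
#' @param n_levels requested number of levels (>= 1).
#' @return List of image matrices, coarsest last.
#' @export
build_pyramid <- function(image, scale_factor = 1.2, n_levels = 8) {
  assert_gray_image(image, min_side = 31)
  stopifnot(n_levels >= 1, scale_factor > 1)
  h0 <- nrow(image); w0 <- ncol(image)
  levels <- list(image)
  if (n_levels == 1) return(levels)
  # smoothing that roughly matches the information loss of one decimation
  sigma <- 0.5 * sqrt(scale_factor^2 - 1)
  prev <- image
  for (k in seq_len(n_levels - 1)) {
    hk <- floor(h0 / scale_factor^k)
    wk <- floor(w0 / scale_factor^k)
    if (min(hk, wk) < 31) break
    im <- EBImage::Image(t(prev))
    im <- EBImage::gblur(im, sigma = sigma)
    im <- EBImage::resize(im, w = wk, h = hk, filter = "bilinear")
    lvl <- t(EBImage::imageData(im))
    lvl[lvl < 0] <- 0
    lvl[lvl > 255] <- 255
    levels[[k + 1]] <- lvl
    prev <- lvl
  }
  levels
}

#' FAST segment test at a single pixel
#'
#' A pixel is a corner when at least `eta` contiguous pixels on the 16-pixel
#' Bresenham circle of radius 3 are all brighter than the centre plus
#' `lambda_t`, or all darker than the centre minus `lambda_t`; runs wrap
#' around the circle. The score is the largest sum of absolute differences
#' to the centre over any qualifying run.
#'
#' @param image image matrix.
#' @param x,y 0-based pixel coordinates (x = column, y = row).
#' @param params a [detector_params()] object.
#' @return List with `is_corner`, `score` and `run_length` (longest
#'   brighter-or-darker run found, qualifying or not).
#' @export
fast_corner_test <- function(image, x, y, params = detector_params()) {
  assert_gray_image(image)
  r <- params$radius
  if (x < r || y < r || x >= ncol(image) - r || y >= nrow(image) - r)
    stop("pixel too close to edge for the segment test", call. = FALSE)
  fast_corner_cpp(image, as.integer(x), as.integer(y),
                  params$lambda_t, as.integer(params$eta))
}

#' Harris corner measure at a single pixel
#'
#' `det(M) - k * trace(M)^2` for the second-moment matrix `M` of
#' central-difference gradients over a 7x7 window, Gaussian-weighted with
#' sigma = 1.
#'
#' @inheritParams fast_corner_test
#' @param k Harris constant.
#' @return Numeric score (positive for corners, <= 0 for edges/flat areas).
#' @export
harris_score <- function(image, x, y, k = 0.04) {
  assert_gray_image(image)
  if (x < 4 || y < 4 || x >= ncol(image) - 4 || y >= nrow(image) - 4)
    stop("gradient window outside image", call. = FALSE)
  harris_cpp(image, as.integer(x), as.integer(y), k)[1]
}

#' Intensity-centroid orientation at a single pixel
#'
#' Orientation is the direction from the pixel to the intensity centroid of
#' the disc of `patch_radius` around it: `atan2(m01, m10)` with moments
#' `m_pq = sum a^p b^q I(a, b)` over disc offsets `(a, b)`. Returns a value
#' in `[-pi, pi)`; a radially symmetric (zero-moment) patch yields 0.
#'
#' @inheritParams fast_corner_test
#' @param patch_radius disc radius in pixels.
#' @return Orientation in radians, measured from +x (rightward) toward +y
#'   (downward).
#' @export
compute_orientation <- function(image, x, y, patch_radius = 15) {
  assert_gray_image(image)
  r <- patch_radius
  if (x < r || y < r || x >= ncol(image) - r || y >= nrow(image) - r)
    stop("orientation patch outside image", call. = FALSE)
  orientation_cpp(image, as.integer(x), as.integer(y), as.integer(r))[1]
}

#' Detect multi-scale oriented keypoints
#'
#' Runs the FAST segment test at every pyramid level (respecting the edge
#' margin), applies 3x3 non-maximum suppression on the segment-test score,
#' scores survivors with the Harris measure, pools candidates across levels,
#' and keeps the `n_keypoints` highest-Harris keypoints. Each keypoint gets
#' an intensity-centroid orientation computed at its detection level (on a
#' copy smoothed by `orientation_blur_sigma`), and its coordinates are
#' rescaled into the level-0 frame with pixel-centre alignment.
#'
#' @param image image matrix.
#' @param params a [detector_params()] object.
#' @return Data frame with columns `x`, `y` (level-0 frame, 0-based), `level`,
#'   `orientation`, `score` (Harris), and the detection-level coordinates
#'   `x_lvl`, `y_lvl`.
#' @export
detect_keypoints <- function(image, params = detector_params()) {
  pyr <- build_pyramid(image, params$scale_factor, params$n_levels)
  h0 <- nrow(image); w0 <- ncol(image)
  per_level <- vector("list", length(pyr))
  for (k in seq_along(pyr)) {
    img <- pyr[[k]]
    det <- fast_detect_cpp(img, params$lambda_t, as.integer(params$eta),
                           as.integer(params$margin))
    if (nrow(det) == 0) next
    hs <- harris_cpp(img, det$x, det$y, params$harris_k)
    per_level[[k]] <- data.frame(x_lvl = det$x, y_lvl = det$y,
                                 level = k - 1L, score = hs)
  }
  kp <- do.call(rbind, per_level)
  empty <- data.frame(x = numeric(0), y = numeric(0), level = integer(0),
                      orientation = numeric(0), score = numeric(0),
                      x_lvl = integer(0), y_lvl = integer(0))
  if (is.null(kp) || nrow(kp) == 0) return(empty)
  ord <- order(-kp$score, kp$level, kp$y_lvl, kp$x_lvl)
  kp <- kp[ord, , drop = FALSE]
  if (nrow(kp) > params$n_keypoints)
    kp <- kp[seq_len(params$n_keypoints), , drop = FALSE]
  kp$orientation <- NA_real_
  kp$x <- NA_real_; kp$y <- NA_real_
  for (k in sort(unique(kp$level))) {
    sel <- kp$level == k
    img <- pyr[[k + 1]]
    oimg <- blur_image(img, params$orientation_blur_sigma)
    kp$orientation[sel] <- orientation_cpp(oimg, kp$x_lvl[sel],
                                           kp$y_lvl[sel], 15L)
    # pixel-centre mapping into the level-0 frame
    kp$x[sel] <- (kp$x_lvl[sel] + 0.5) * (w0 / ncol(img)) - 0.5
    kp$y[sel] <- (kp$y_lvl[sel] + 0.5) * (h0 / nrow(img)) - 0.5
  }
  rownames(kp) <- NULL
  kp[, c("x", "y", "level", "orientation", "score", "x_lvl", "y_lvl")]
}

# Gaussian-smooth an intensity matrix, clamped back to [0, 255].
blur_image <- function(img, sigma) {
  if (sigma <= 0) return(img)
  out <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(img)),
                                             sigma = sigma)))
  out[out < 0] <- 0
  out[out > 255] <- 255
  out
}

#' Compute a rotated binary descriptor for one keypoint
#'
#' Bit `i` is 1 iff `I(p1_i') < I(p2_i')` on the descriptor image — the
#' input smoothed by `blur_sigma` — where the pattern pair offsets are
#' rotated by the keypoint orientation (quantized to `rotation_bins` bins,
#' offsets rounded to the pixel grid) and translated to the keypoint.
#' Coordinates in `kp` are interpreted in the frame of `image` (for a
#' multi-scale keypoint, pass its detection-level image and `x_lvl`/`y_lvl`).
#'
#' @param image image matrix.
#' @param kp list or one-row data frame with `x`, `y`, `orientation`.
#' @param pattern test pattern from [brief_pattern()] or
#'   [generate_brief_pattern()].
#' @param blur_sigma pre-smoothing of the comparison image (0 = compare raw
#'   pixel intensities).
#' @param rotation_bins orientation quantization bins.
#' @return Raw vector of 32 bytes (256 bits, LSB-first per byte as unpacked
#'   by [descriptor_bits()]).
#' @export
compute_descriptor <- function(image, kp, pattern = brief_pattern(),
                               blur_sigma = 2, rotation_bins = 120) {
  assert_gray_image(image)
  pattern <- validate_pattern(pattern)
  img <- blur_image(image, blur_sigma)
  res <- descriptors_cpp(img, as.integer(kp$x), as.integer(kp$y),
                         as.numeric(kp$orientation), pattern,
                         as.integer(rotation_bins))
  if (!res$ok[1])
    stop("keypoint too close to edge for descriptor patch", call. = FALSE)
  res$descriptors[, 1]
}

#' Detect keypoints and compute their descriptors
#'
#' Composition of [detect_keypoints()] and the descriptor stage; keypoints
#' whose rotated descriptor patch escapes the image at their detection level
#' are dropped from both outputs, so the two are index-aligned.
#'
#' @inheritParams detect_keypoints
#' @param pattern binary test pattern.
#' @return List with `keypoints` (data frame as in [detect_keypoints()]) and
#'   `descriptors` (raw matrix, 32 rows x one column per keypoint).
#' @export
detect_and_describe <- function(image, params = detector_params(),
                                pattern = brief_pattern()) {
  pattern <- validate_pattern(pattern)
  kp <- detect_keypoints(image, params)
  if (nrow(kp) == 0)
    return(list(keypoints = kp, descriptors = matrix(raw(0), 32, 0)))
  pyr <- build_pyramid(image, params$scale_factor, params$n_levels)
  desc <- matrix(as.raw(0), 32, nrow(kp))
  keep <- logical(nrow(kp))
  for (k in sort(unique(kp$level))) {
    sel <- which(kp$level == k)
    dimg <- blur_image(pyr[[k + 1]], params$blur_sigma)
    res <- descriptors_cpp(dimg, kp$x_lvl[sel], kp$y_lvl[sel],
                           kp$orientation[sel], pattern,
                           params$rotation_bins)
    desc[, sel] <- res$descriptors
    keep[sel] <- res$ok
  }
  kp <- kp[keep, , drop = FALSE]
  rownames(kp) <- NULL
  list(keypoints = kp, descriptors = desc[, keep, drop = FALSE])
}

#' Unpack a binary descriptor to 0/1 bits
#'
#' @param descriptors raw vector (one descriptor) or raw matrix (one column
#'   per descriptor).
#' @return Integer matrix of 0/1 with 256 rows, one column per descriptor.
#' @export
descriptor_bits <- function(descriptors) {
  if (is.matrix(descriptors)) {
    if (ncol(descriptors) == 0) return(matrix(integer(0), 256, 0))
    apply(descriptors, 2, function(d) as.integer(rawToBits(d)))
  } else {
    matrix(as.integer(rawToBits(descriptors)), ncol = 1)
  }
}
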