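#' Keypoint detector parameters
#'
#' Parameters for multi-scale FAST corner detection with Harris ranking.
#' Defaults follow routine AOSLO montaging practice: an intensity threshold
#' of 21 grey levels, arc length 9 on the 16-pixel circle of radius 3, and
#' the top 5000 keypoints pooled over an 8-level pyramid with scale factor
#' 1.2. Keypoints are kept at least `margin` pixels from every image edge at
#' their detection level so that the 31x31 descriptor patch fits.
#'
#' @param lambda_t intensity threshold (grey levels) for the segment test.
#' @param eta minimum number of contiguous qualifying arc pixels (1..16).
#' @param n_keypoints maximum number of keypoints retained after ranking.
#' @param n_levels number of pyramid levels.
#' @param scale_factor per-level downsampling ratio (> 1).
#' @param margin minimum distance (px) of a keypoint from each image edge.
#' @param harris_k Harris corner-measure constant.
#' @param blur_sigma Gaussian smoothing (px) applied to each pyramid level
#'   before descriptor bits are sampled (detection and orientation use the
#'   unsmoothed level). Smoothing the comparison image is what makes
#'   single-pixel binary tests repeatable under noise and resampling; 0
#'   disables it.
#' @param rotation_bins number of orientation quantization bins for the
#'   rotated descriptor pattern (bins of `360 / rotation_bins` degrees).
#' @param orientation_blur_sigma Gaussian smoothing (px) of the image used
#'   for the intensity-centroid orientation. The centroid direction of a
#'   quasi-periodic photoreceptor mosaic is a weak signal; estimating it on
#'   a smoothed copy suppresses resampling jitter and makes the assigned
#'   angle repeatable. 0 uses the raw level.
#' @return A list of class `detector_params`.
#' @export
detector_params <- function(lambda_t = 21, eta = 9, n_keypoints = 5000,
                            n_levels = 8, scale_factor = 1.2, margin = 15,
                            harris_k = 0.04, blur_sigma = 2,
                            rotation_bins = 120, orientation_blur_sigma = 4) {
  stopifnot(lambda_t > 0, eta >= 1, eta <= 16, n_keypoints > 0,
            n_levels >= 1, scale_factor > 1, margin >= 3, blur_sigma >= 0,
            rotation_bins >= 1, orientation_blur_sigma >= 0)
  structure(list(lambda_t = lambda_t, eta = eta, n_keypoints = n_keypoints,
                 n_levels = n_levels, scale_factor = scale_factor,
                 margin = margin, harris_k = harris_k, radius = 3L,
                 blur_sigma = blur_sigma,
                 rotation_bins = as.integer(rotation_bins),
                 orientation_blur_sigma = orientation_blur_sigma),
            class = "detector_params")
}

#' Descriptor matcher parameters
#'
#' Controls the ratio test and the Hamming-space LSH index. The ratio test
#' accepts a putative match only when the best candidate's distance is less
#' than `ratio` times the second-best distance. The LSH index uses `b`
#' bit-sampling hash tables of `key_bits` sampled bit positions each.
#'
#' @param ratio ratio-test threshold in (0, 1).
#' @param b number of hash tables (buckets per stored descriptor).
#' @param key_bits sampled bit positions per table.
#' @param use_lsh if `FALSE`, match by exact brute-force 2-NN instead.
#' @return A list of class `matcher_params`.
#' @export
matcher_params <- function(ratio = 0.75, b = 6, key_bits = 16,
                           use_lsh = TRUE) {
  stopifnot(ratio > 0, ratio < 1, b >= 1, key_bits >= 1, key_bits <= 30)
  structure(list(ratio = ratio, b = as.integer(b),
                 key_bits = as.integer(key_bits), use_lsh = isTRUE(use_lsh)),
            class = "matcher_params")
}

#' RANSAC parameters for translation estimation
#'
#' @param iterations number of single-correspondence samples to score. When
#'   the number of putative matches does not exceed `iterations`, every match
#'   is tried once (an exhaustive, deterministic scan); random sampling is
#'   used only when there are more matches than iterations.
#' @param delta inlier residual threshold in pixels (boundary inclusive).
#' @param seed seed for the sampling stage.
#' @return A list of class `ransac_params`.
#' @export
ransac_params <- function(iterations = 1000, delta = 10, seed = 0) {
  stopifnot(iterations >= 1, delta > 0)
  structure(list(iterations = as.integer(iterations), delta = delta,
                 seed = as.integer(seed)),
            class = "ransac_params")
}

#' Montage-growing parameters
#'
#' `T1` is the immediate-accept inlier count: while scanning candidate
#' destination tiles, the first alignment with more than `T1` inliers is
#' taken as good enough and the scan stops. `T2` is the fallback: after all
#' candidates are scanned, the best alignment is accepted if it has more
#' than `T2` inliers. `d` bounds the nominal (fixation-target) distance, in
#' degrees, within which tile pairs are compared at all.
#'
#' @param T1 immediate-accept inlier threshold (strict `>`).
#' @param T2 best-accept inlier threshold (strict `>`).
#' @param d nominally-close distance (degrees of visual angle).
#' @param seed seed for random tile-of-reference and sweep-order choices.
#' @return A list of class `montage_params`.
#' @export
montage_params <- function(T1 = 50, T2 = 10, d = 7, seed = 0) {
  stopifnot(T1 >= T2, T2 >= 1, d > 0)
  structure(list(T1 = T1, T2 = T2, d = d, seed = as.integer(seed)),
            class = "montage_params")
}
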