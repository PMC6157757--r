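#' Translation implied by a single match
#'
#' The minimal sample for a translation model is one correspondence:
#' `(tx, ty) = destination - source`.
#'
#' @param m one-row match (with `query_index`, `train_index`).
#' @param src_keypoints,dst_keypoints keypoint data frames.
#' @return Numeric `c(tx, ty)` in pixels.
#' @export
translation_from_match <- function(m, src_keypoints, dst_keypoints) {
  i <- m$query_index; j <- m$train_index
  if (i < 1 || i > nrow(src_keypoints) || j < 1 || j > nrow(dst_keypoints))
    stop("match indexes invalid keypoint", call. = FALSE)
  c(tx = dst_keypoints$x[j] - src_keypoints$x[i],
    ty = dst_keypoints$y[j] - src_keypoints$y[i])
}

#' Count inliers of a candidate translation
#'
#' A match is an inlier when the Euclidean distance between the translated
#' source keypoint and its destination keypoint is at most `delta`
#' (boundary inclusive).
#'
#' @param t numeric `c(tx, ty)`.
#' @param matches match data frame with `query_x`, `query_y`, `train_x`,
#'   `train_y` columns.
#' @param delta inlier threshold in pixels.
#' @return List with `count` and `inliers` (row indices into `matches`).
#' @export
count_inliers <- function(t, matches, delta = 10) {
  ex <- matches$query_x + t[1] - matches$train_x
  ey <- matches$query_y + t[2] - matches$train_y
  inl <- which(ex * ex + ey * ey <= delta^2)
  list(count = length(inl), inliers = inl)
}

#' Estimate the aligning translation between two tiles by RANSAC
#'
#' Each iteration samples one match, forms the candidate translation it
#' implies, and counts inliers within `delta` pixels; the candidate with
#' most inliers wins (ties: first encountered). When the number of matches
#' does not exceed `iterations`, all matches are tried once in order, which
#' makes the scan exhaustive and deterministic. The winning translation is
#' refined as the component-wise mean of its inlier displacements, and the
#' inlier set is recounted under the refined translation.
#'
#' @param matches match data frame (as from [match_tiles()]); coordinates
#'   are used directly, so keypoint frames must be consistent.
#' @param params a [ransac_params()] object.
#' @return `NULL` for an empty match list; otherwise a `tile_transform`
#'   list with `tx`, `ty`, `inlier_count`, `inliers` (row indices), and
#'   `consensus_count`, the best candidate's inlier count before refinement
#'   (the quantity thresholded by the acceptance rules).
#' @export
ransac_align <- function(matches, params = ransac_params()) {
  n <- nrow(matches)
  if (is.null(n) || n == 0) return(NULL)
  cand <- if (n <= params$iterations) seq_len(n)
          else with_seed_local(params$seed,
                               sample.int(n, params$iterations,
                                          replace = TRUE))
  scan <- ransac_scan_cpp(matches$query_x, matches$query_y,
                          matches$train_x, matches$train_y,
                          as.integer(cand), params$delta)
  j <- cand[scan$best_k]
  t0 <- c(matches$train_x[j] - matches$query_x[j],
          matches$train_y[j] - matches$query_y[j])
  ci <- count_inliers(t0, matches, params$delta)
  t1 <- c(mean(matches$train_x[ci$inliers] - matches$query_x[ci$inliers]),
          mean(matches$train_y[ci$inliers] - matches$query_y[ci$inliers]))
  cf <- count_inliers(t1, matches, params$delta)
  structure(list(tx = t1[1], ty = t1[2],
                 inlier_count = cf$count, inliers = cf$inliers,
                 consensus_count = ci$count),
            class = "tile_transform")
}
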