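#' Hamming distance between two binary descriptors
#'
#' @param d1,d2 raw vectors of equal length (32 bytes for the default
#'   256-bit descriptors).
#' @return Integer count of differing bits.
#' @export
hamming_distance <- function(d1, d2) {
  if (!is.raw(d1) || !is.raw(d2) || length(d1) != length(d2))
    stop("descriptors must be raw vectors of equal length", call. = FALSE)
  hamming_cpp(d1, d2)
}

#' Build a bit-sampling LSH index over binary descriptors
#'
#' Each of the `b` hash tables samples `key_bits` fixed bit positions
#' (chosen by `seed`) from the 256-bit descriptor; a descriptor is stored in
#' one bucket per table. Querying compares a query exhaustively against the
#' union of its buckets, so identical descriptors always collide and the
#' reported distances are exact Hamming distances over the candidate set.
#'
#' @param descriptors raw matrix, one descriptor per column.
#' @param params a [matcher_params()] object.
#' @param seed seed for the sampled bit positions.
#' @return An object of class `lsh_index`.
#' @export
build_lsh_index <- function(descriptors, params = matcher_params(),
                            seed = 0) {
  if (!is.matrix(descriptors) || !is.raw(descriptors) ||
      ncol(descriptors) == 0)
    stop("need a non-empty raw descriptor matrix", call. = FALSE)
  nbits <- nrow(descriptors) * 8L
  bitpos <- with_seed_local(seed, {
    vapply(seq_len(params$b),
           function(i) sample.int(nbits, params$key_bits) - 1L,
           integer(params$key_bits))
  })
  bitpos <- matrix(as.integer(bitpos), nrow = params$key_bits)
  keys <- lsh_keys_cpp(descriptors, bitpos)
  structure(list(descriptors = descriptors, bitpos = bitpos, keys = keys,
                 b = params$b, key_bits = params$key_bits,
                 seed = as.integer(seed)),
            class = "lsh_index")
}

#' Approximate two nearest neighbours via LSH
#'
#' The candidate set is the union of the query's buckets across all tables.
#' The true nearest neighbour is missed when it shares no bucket with the
#' query, so the returned best distance is an upper bound on the exact one.
#'
#' @param index an [build_lsh_index()] object.
#' @param query a single raw descriptor.
#' @return List with `best` and `second`, each `NULL` or a list
#'   `(index, distance)` (1-based index into the stored descriptors).
#' @export
lsh_2nn <- function(index, query) {
  stopifnot(inherits(index, "lsh_index"))
  qk <- lsh_keys_cpp(matrix(query, ncol = 1), index$bitpos)
  res <- lsh2nn_cpp(index$descriptors, index$keys,
                    matrix(query, ncol = 1), qk)
  pick <- function(i, d) if (is.na(i)) NULL else list(index = i, distance = d)
  list(best = pick(res[1, 1], res[1, 2]),
       second = pick(res[1, 3], res[1, 4]))
}

#' Exact two nearest neighbours by brute force
#'
#' Exhaustive Hamming scan; ties broken by the lower stored index. This is
#' the exact counterpart (and test oracle) of [lsh_2nn()].
#'
#' @param descriptors raw matrix of stored descriptors (columns).
#' @param query a single raw descriptor.
#' @return As [lsh_2nn()].
#' @export
brute_force_2nn <- function(descriptors, query) {
  if (!is.matrix(descriptors) || ncol(descriptors) == 0)
    stop("need at least one stored descriptor", call. = FALSE)
  res <- brute2nn_cpp(descriptors, matrix(query, ncol = 1))
  pick <- function(i, d) if (is.na(i)) NULL else list(index = i, distance = d)
  list(best = pick(res[1, 1], res[1, 2]),
       second = pick(res[1, 3], res[1, 4]))
}

# Shared batch 2-NN + ratio test. train may be a raw matrix or lsh_index.
ratio_test_core <- function(query_desc, train, ratio, use_lsh, lsh_seed = 0,
                            params = matcher_params()) {
  if (use_lsh) {
    index <- if (inherits(train, "lsh_index")) train
             else build_lsh_index(train, params, seed = lsh_seed)
    qk <- lsh_keys_cpp(query_desc, index$bitpos)
    nn <- lsh2nn_cpp(index$descriptors, index$keys, query_desc, qk)
  } else {
    train_desc <- if (inherits(train, "lsh_index")) train$descriptors
                  else train
    nn <- brute2nn_cpp(train_desc, query_desc)
  }
  ok <- !is.na(nn[, 3]) & !is.na(nn[, 1]) & nn[, 2] < ratio * nn[, 4]
  data.frame(query_index = which(ok), train_index = nn[ok, 1],
             distance = nn[ok, 2])
}

#' Match two feature sets with the ratio test
#'
#' For each query descriptor the two nearest stored descriptors are found
#' (approximately via LSH, or exactly); the best is accepted only when its
#' distance is less than `ratio` times the second-best distance. Queries
#' with fewer than two candidates are rejected.
#'
#' @param query_features,train_features lists with `keypoints` and
#'   `descriptors` as returned by [detect_and_describe()].
#' @param params a [matcher_params()] object.
#' @param lsh_seed seed for the LSH bit sampling.
#' @return Data frame of accepted matches: `query_index`, `train_index`,
#'   `distance`, plus the matched keypoint coordinates `query_x`, `query_y`,
#'   `train_x`, `train_y` (level-0 frames).
#' @export
ratio_test_match <- function(query_features, train_features,
                             params = matcher_params(), lsh_seed = 0) {
  qd <- query_features$descriptors
  td <- train_features$descriptors
  if (ncol(qd) == 0 || ncol(td) == 0)
    stop("both feature sets must be non-empty", call. = FALSE)
  m <- ratio_test_core(qd, td, params$ratio, params$use_lsh, lsh_seed, params)
  qk <- query_features$keypoints
  tk <- train_features$keypoints
  m$query_x <- qk$x[m$query_index]
  m$query_y <- qk$y[m$query_index]
  m$train_x <- tk$x[m$train_index]
  m$train_y <- tk$y[m$train_index]
  m
}

#' Match two tiles across all shared modalities
#'
#' Runs the ratio-test matcher independently for each modality present in
#' both tiles and returns the union of the per-modality match sets, with
#' modality labels preserved. The modalities of a tile are acquired in
#' perfect spatial registration, so all matched coordinates live in the
#' common tile pixel frame and can be pooled for transform estimation.
#'
#' @param tileA_features,tileB_features named lists (by modality) of feature
#'   sets, as built by [prepare_tiles()]; `tileA` supplies the queries.
#' @param params a [matcher_params()] object.
#' @param lsh_seed seed used when building throwaway LSH indexes.
#' @return Data frame of matches with a `modality` column.
#' @export
match_tiles <- function(tileA_features, tileB_features,
                        params = matcher_params(), lsh_seed = 0) {
  shared <- intersect(names(tileA_features), names(tileB_features))
  shared <- shared[vapply(shared, function(m) {
    ncol(tileA_features[[m]]$descriptors) > 0 &&
      ncol(tileB_features[[m]]$descriptors) > 0
  }, logical(1))]
  if (length(shared) == 0)
    stop("tiles share no modality with features", call. = FALSE)
  out <- lapply(shared, function(mod) {
    fa <- tileA_features[[mod]]
    fb <- tileB_features[[mod]]
    train <- if (!is.null(fb$lsh)) fb$lsh else fb$descriptors
    m <- ratio_test_core(fa$descriptors, train, params$ratio,
                         params$use_lsh, lsh_seed, params)
    m$query_x <- fa$keypoints$x[m$query_index]
    m$query_y <- fa$keypoints$y[m$query_index]
    m$train_x <- fb$keypoints$x[m$train_index]
    m$train_y <- fb$keypoints$y[m$train_index]
    if (nrow(m) > 0) m$modality <- mod
    else m$modality <- character(0)
    m
  })
  do.call(rbind, out)
}
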