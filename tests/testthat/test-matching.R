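rand_desc <- function(n, seed = 1) {
  set.seed(seed)
  matrix(as.raw(sample(0:255, 32 * n, TRUE)), 32, n)
}

flip_bits <- function(d, bits) {
  for (b in bits)
    d[b %/% 8 + 1] <- xor(d[b %/% 8 + 1], as.raw(bitwShiftL(1, b %% 8)))
  d
}

test_that("Hamming distance counts differing bits", {
  d <- rand_desc(1)[, 1]
  expect_equal(hamming_distance(d, d), 0)
  expect_equal(hamming_distance(rep(as.raw(0), 32), rep(as.raw(255), 32)),
               256)
  d0 <- rep(as.raw(0), 32)
  expect_equal(hamming_distance(d0, flip_bits(d0, c(3, 17, 200))), 3)
  expect_error(hamming_distance(d0, d0[1:16]), "equal length")
})

test_that("LSH index places each descriptor in one bucket per table", {
  one <- rand_desc(1)
  idx <- build_lsh_index(one, matcher_params(), seed = 3)
  expect_equal(dim(idx$keys), c(1L, 6L))   # 6 tables = 6 buckets

  two <- cbind(one, one)
  idx2 <- build_lsh_index(two, matcher_params(), seed = 3)
  expect_equal(idx2$keys[1, ], idx2$keys[2, ])  # identical -> same keys

  # 1000 random descriptors spread thinly over 2^16 buckets per table
  idx3 <- build_lsh_index(rand_desc(1000, 5), matcher_params(), seed = 3)
  occ <- apply(idx3$keys, 2, function(k) table(k))
  expect_true(all(vapply(occ, max, 1) <= 4))
  expect_true(all(vapply(occ, length, 1) > 950))

  expect_error(build_lsh_index(matrix(raw(0), 32, 0)), "non-empty")
})

test_that("LSH 2-NN is sound and bounded by the exact search", {
  train <- rand_desc(500, 7)
  idx <- build_lsh_index(train, matcher_params(), seed = 9)

  # stored descriptor as query: guaranteed self-collision, distance 0
  r <- lsh_2nn(idx, train[, 17])
  expect_equal(r$best$index, 17)
  expect_equal(r$best$distance, 0)

  set.seed(11)
  for (i in 1:50) {
    q <- flip_bits(train[, sample(500, 1)], sample(0:255, sample(0:40, 1)))
    lr <- lsh_2nn(idx, q)
    br <- brute_force_2nn(train, q)
    if (!is.null(lr$best)) {
      # reported distance is a true recomputed Hamming distance ...
      expect_equal(lr$best$distance,
                   hamming_distance(q, train[, lr$best$index]))
      # ... and never beats the exact optimum
      expect_gte(lr$best$distance, br$best$distance)
    }
  }
})

test_that("brute-force 2-NN equals an independent exhaustive scan", {
  train <- rand_desc(100, 13)
  set.seed(14)
  for (i in 1:20) {
    q <- rand_desc(1, 100 + i)[, 1]
    r <- brute_force_2nn(train, q)
    d <- vapply(seq_len(100), function(j) hamming_distance(q, train[, j]),
                1L)
    o <- order(d)  # stable: ties by lower index
    expect_equal(r$best$index, o[1])
    expect_equal(r$best$distance, d[o[1]])
    expect_equal(r$second$index, o[2])
    expect_equal(r$second$distance, d[o[2]])
  }
  one <- rand_desc(1, 15)
  r <- brute_force_2nn(one, one[, 1])
  expect_equal(r$best$distance, 0)
  expect_null(r$second)
  expect_error(brute_force_2nn(matrix(raw(0), 32, 0), one[, 1]))
})

test_that("ratio test applies the 2-NN distance criterion", {
  # construct query/train sets with controlled distances
  base <- rep(as.raw(0), 32)
  mk <- function(nbits, bits = seq_len(nbits) - 1) flip_bits(base, bits)
  kp <- function(n) data.frame(x = seq_len(n), y = seq_len(n), level = 0,
                               orientation = 0, score = 1)
  # best at distance 10, second at 50: 10 < 0.75 * 50 -> accepted
  train <- cbind(mk(10), mk(50, 100:149))
  q <- list(keypoints = kp(1), descriptors = matrix(base, 32, 1))
  tr <- list(keypoints = kp(2), descriptors = train)
  m <- ratio_test_match(q, tr, matcher_params(use_lsh = FALSE))
  expect_equal(nrow(m), 1)
  expect_equal(m$train_index, 1)
  expect_equal(m$distance, 10)

  # best 40, second 50: 40 >= 37.5 -> rejected
  train2 <- cbind(mk(40), mk(50, 100:149))
  tr2 <- list(keypoints = kp(2), descriptors = train2)
  expect_equal(nrow(ratio_test_match(q, tr2,
                                     matcher_params(use_lsh = FALSE))), 0)

  # single stored descriptor: no second neighbour, always rejected
  tr1 <- list(keypoints = kp(1), descriptors = matrix(mk(1), 32, 1))
  expect_equal(nrow(ratio_test_match(q, tr1,
                                     matcher_params(use_lsh = FALSE))), 0)
})

test_that("lowering the ratio threshold never adds matches", {
  img <- fx_scene()$confocal[1:300, 1:300]
  f <- detect_and_describe(img)
  n_prev <- Inf
  for (r in c(0.9, 0.75, 0.5, 0.3)) {
    n <- nrow(ratio_test_match(f, f, matcher_params(ratio = r,
                                                    use_lsh = FALSE)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("multimodal matching unions per-modality match sets", {
  tiles <- fx_small_grid()$tiles
  prep <- prepare_tiles(tiles[1:2], seed = 0)
  fa <- prep[[1]]$features
  fb <- prep[[2]]$features

  m <- match_tiles(fa, fb, matcher_params())
  expect_true(all(m$modality %in% c("confocal", "split", "dark")))
  # restriction to one modality equals matching that modality alone
  for (mod in c("confocal", "dark")) {
    alone <- match_tiles(fa[mod], fb[mod], matcher_params())
    sub <- m[m$modality == mod, ]
    rownames(sub) <- NULL
    expect_equal(sub, alone)
  }
  expect_error(match_tiles(fa["confocal"], fb["dark"], matcher_params()),
               "modality")

  # a tile matched against itself recovers near-zero displacements
  self <- match_tiles(fa, fa, matcher_params())
  disp <- sqrt((self$query_x - self$train_x)^2 +
                 (self$query_y - self$train_y)^2)
  expect_gte(mean(disp < 1), 0.9)
})
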