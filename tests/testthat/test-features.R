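test_that("pyramid levels have the prescribed geometry", {
  img <- matrix(round(runif(512 * 512, 0, 255)), 512, 512)
  pyr <- build_pyramid(img, scale_factor = 2, n_levels = 3)
  expect_length(pyr, 3)
  expect_equal(vapply(pyr, nrow, 1L), c(512L, 256L, 128L))
  expect_identical(pyr[[1]], img)

  expect_identical(build_pyramid(img, n_levels = 1), list(img))

  img400 <- matrix(round(runif(400 * 400, 0, 255)), 400, 400)
  pyr <- build_pyramid(img400, scale_factor = 1.2, n_levels = 8)
  expect_length(pyr, 8)
  expect_equal(nrow(pyr[[8]]), floor(400 / 1.2^7))  # = 111
  # levels below the 31 px descriptor patch are dropped
  tiny <- matrix(round(runif(64 * 64, 0, 255)), 64, 64)
  pyr <- build_pyramid(tiny, scale_factor = 2, n_levels = 5)
  expect_true(all(vapply(pyr, nrow, 1L) >= 31))
  expect_error(build_pyramid(matrix(0, 20, 20)), "too small")
})

test_that("segment test matches the exhaustive arc-run oracle", {
  set.seed(42)
  p <- detector_params()
  for (i in 1:1000) {
    patch <- matrix(sample(0:255, 49, TRUE), 7, 7)
    got <- fast_corner_test(patch, 3, 3, p)
    want <- fast_oracle(patch, p$lambda_t, p$eta)
    expect_identical(got$is_corner, want$is_corner)
    expect_identical(got$run_length, want$run_length)
  }
})

test_that("segment test handles canonical corner configurations", {
  p <- detector_params()
  uni <- matrix(100, 9, 9)
  r <- fast_corner_test(uni, 4, 4, p)
  expect_false(r$is_corner)
  expect_equal(r$score, 0)

  cx <- c(0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3, -3, -3, -2, -1)
  cy <- c(-3, -3, -2, -1, 0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3)
  # 11 contiguous brighter arc pixels: a corner (11 >= 9)
  img <- matrix(100, 9, 9)
  for (i in 1:11) img[5 + cy[i], 5 + cx[i]] <- 255
  r <- fast_corner_test(img, 4, 4, p)
  expect_true(r$is_corner)
  expect_equal(r$run_length, 11L)
  expect_equal(r$score, 11 * 155)

  # exactly 8 contiguous: below the eta = 9 requirement
  img <- matrix(100, 9, 9)
  for (i in 1:8) img[5 + cy[i], 5 + cx[i]] <- 255
  expect_false(fast_corner_test(img, 4, 4, p)$is_corner)

  expect_error(fast_corner_test(uni, 1, 4, p), "edge")
})

test_that("Harris measure separates flat areas, edges and corners", {
  flat <- matrix(77, 15, 15)
  expect_equal(harris_score(flat, 7, 7), 0)
  step <- cbind(matrix(0, 15, 8), matrix(255, 15, 7))
  expect_lte(harris_score(step, 7, 7), 0)
  checker <- 255 * outer(1:15, 1:15, function(i, j) (i > 8) == (j > 8))
  expect_gt(harris_score(checker, 7, 7), 0)
  expect_error(harris_score(flat, 1, 7), "window")
})

test_that("intensity-centroid orientation follows the brightness offset", {
  sym <- matrix(10, 41, 41)
  sym[21, 21] <- 255
  expect_equal(compute_orientation(sym, 20, 20), 0)

  right <- matrix(10, 41, 41)
  right[21, 29] <- 255  # bright pixel at +x
  expect_equal(compute_orientation(right, 20, 20), 0)

  below <- matrix(10, 41, 41)
  below[29, 21] <- 255  # bright pixel at +y (row-down)
  expect_equal(compute_orientation(below, 20, 20), pi / 2)

  left <- matrix(10, 41, 41)
  left[21, 13] <- 255
  expect_equal(compute_orientation(left, 20, 20), -pi)  # [-pi, pi) range
  expect_error(compute_orientation(sym, 5, 20), "patch")
})

test_that("keypoint detection respects margin, cap and locates structure", {
  expect_equal(nrow(detect_keypoints(matrix(128, 100, 100))), 0)

  img <- fx_scene()$confocal[1:300, 1:300]
  p <- detector_params()
  kp <- detect_keypoints(img, p)
  expect_lte(nrow(kp), p$n_keypoints)
  expect_true(all(kp$x_lvl >= p$margin) && all(kp$y_lvl >= p$margin))
  # margin holds at the detection level for every pyramid level used
  pyr <- build_pyramid(img, p$scale_factor, p$n_levels)
  for (k in unique(kp$level)) {
    s <- kp$level == k
    expect_true(all(kp$x_lvl[s] < ncol(pyr[[k + 1]]) - p$margin))
    expect_true(all(kp$y_lvl[s] < nrow(pyr[[k + 1]]) - p$margin))
  }
  # cap engages when candidates exceed n_keypoints
  kp50 <- detect_keypoints(img, detector_params(n_keypoints = 50))
  expect_equal(nrow(kp50), 50)
  expect_true(min(kp50$score) >= sort(kp$score, decreasing = TRUE)[51])

  # three isolated high-contrast corner structures are all found
  iso <- matrix(20, 200, 200)
  corners <- list(c(60, 60), c(140, 70), c(80, 150))  # (x, y)
  for (co in corners)
    iso[co[2] + (0:14), co[1] + (0:14)] <- 235
  kpi <- detect_keypoints(iso)
  for (co in corners) {
    d <- sqrt((kpi$x - co[1])^2 + (kpi$y - co[2])^2)
    expect_lt(min(d), 2)
  }
})

test_that("descriptor bits implement the binary intensity test", {
  # uniform patch: strict inequality fails everywhere -> all bits zero
  uni <- matrix(128, 64, 64)
  d <- compute_descriptor(uni, list(x = 31, y = 31, orientation = 0))
  expect_equal(sum(descriptor_bits(d)), 0)

  # single pair at orientation 0, raw comparison: I(-2,0) < I(3,1) -> 1
  img <- matrix(128, 64, 64)
  img[32 + 0, 32 - 2] <- 10    # (x=-2, y=0) relative to kp (31,31)
  img[32 + 1, 32 + 3] <- 200   # (x=+3, y=+1)
  pat <- matrix(c(-2L, 0L, 3L, 1L), 1, 4)
  d <- compute_descriptor(img, list(x = 31, y = 31, orientation = 0),
                          pattern = pat, blur_sigma = 0)
  expect_equal(as.integer(rawToBits(d)[1]), 1L)
  # flipped pair -> 0
  pat2 <- matrix(c(3L, 1L, -2L, 0L), 1, 4)
  d2 <- compute_descriptor(img, list(x = 31, y = 31, orientation = 0),
                           pattern = pat2, blur_sigma = 0)
  expect_equal(as.integer(rawToBits(d2)[1]), 0L)

  expect_error(
    compute_descriptor(uni, list(x = 2, y = 2, orientation = 0)),
    "edge")
})

test_that("descriptors survive a 90-degree rotation", {
  img <- fx_scene()$confocal[1:300, 1:300]
  rot <- rotate_gray(img, pi / 2, fill = 30)
  kp <- detect_keypoints(img)
  kp <- kp[kp$level == 1, ][1:70, ]
  cx <- (300 - 1) / 2
  rx <- -(kp$y - cx) + cx
  ry <- (kp$x - cx) + cx
  pat <- brief_pattern()
  d <- integer(0)
  for (i in seq_len(nrow(kp))) {
    x0 <- round(kp$x[i]); y0 <- round(kp$y[i])
    x1 <- round(rx[i]); y1 <- round(ry[i])
    if (min(x0, y0, x1, y1) < 22 || max(x0, y0, x1, y1) > 277) next
    o0 <- compute_orientation(blur_image_for_test(img), x0, y0)
    o1 <- compute_orientation(blur_image_for_test(rot), x1, y1)
    d0 <- compute_descriptor(img, list(x = x0, y = y0, orientation = o0))
    d1 <- compute_descriptor(rot, list(x = x1, y = y1, orientation = o1))
    d <- c(d, hamming_distance(d0, d1))
  }
  expect_gte(length(d), 40)
  expect_lte(median(d), 8)
  expect_gte(mean(d <= 32), 0.85)
})

test_that("detect_and_describe keeps keypoints and descriptors aligned", {
  expect_equal(nrow(detect_and_describe(matrix(0, 80, 80))$keypoints), 0)

  img <- fx_scene()$confocal[1:300, 1:300]
  fd <- detect_and_describe(img)
  expect_equal(nrow(fd$keypoints), ncol(fd$descriptors))
  expect_gt(nrow(fd$keypoints), 500)

  # determinism: identical input and parameters give identical output
  fd2 <- detect_and_describe(img)
  expect_identical(fd$keypoints, fd2$keypoints)
  expect_identical(fd$descriptors, fd2$descriptors)
})

test_that("the shipped test pattern is reproducible and valid", {
  pat <- brief_pattern()
  expect_equal(dim(pat), c(256L, 4L))
  expect_true(all(abs(pat) <= 15))
  expect_false(any(pat[, 1] == pat[, 3] & pat[, 2] == pat[, 4]))
  regen <- generate_brief_pattern(seed = 42)
  expect_equal(unname(pat), unname(regen))
})
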