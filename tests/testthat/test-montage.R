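test_that("nominal-position adjacency is Euclidean, symmetric, irreflexive", {
  pos <- data.frame(tile_id = c("a", "b", "c"),
                    x = c(0, 0.5, 8), y = c(0, 0, 0))
  adj <- nominally_close(pos, d = 7)
  expect_equal(adj$a, "b")         # 0.5 <= 7
  expect_equal(adj$b, "a")         # symmetric; 8 - 0.5 = 7.5 > 7
  expect_length(adj$c, 0)          # 8 > 7
  expect_false("a" %in% adj$a)     # irreflexive
  expect_length(nominally_close(pos[1, ], d = 7)$a, 0)
})

test_that("alignment accepts good-enough candidates immediately", {
  prep <- fx_default_prep()
  ids <- names(prep)
  probe <- new.env()
  # an overlapping neighbour first: passes T1, later candidates untouched
  res <- align_to_montage("tile_r1c2", c("tile_r1c1", "tile_r1c3"),
                          prep, probe = probe)
  expect_equal(res$dst_id, "tile_r1c1")
  expect_equal(res$n_evaluated, 1L)
  expect_equal(probe$n_ransac, 1L)
  expect_gt(res$transform$consensus_count, 50)

  # non-overlapping candidates only: no acceptance
  res2 <- align_to_montage("tile_r1c1", "tile_r3c3", prep)
  expect_null(res2)
})

test_that("montage growth partitions tiles and recovers the grid geometry", {
  cv <- fx_small_grid()
  res <- build_montage(cv$tiles, params = montage_params(seed = 2))
  all_ids <- unlist(lapply(res$components, `[[`, "tile_ids"))
  expect_setequal(all_ids, names(cv$tiles))
  expect_equal(anyDuplicated(all_ids), 0L)
  expect_length(res$components, 1)

  # reference tile carries the identity transform
  comp <- res$components[[1]]
  ref_row <- comp$transforms[comp$transforms$tile_id == comp$reference, ]
  expect_equal(c(ref_row$tx, ref_row$ty), c(0, 0))

  # every accepted pairwise translation within 2 px of carved truth
  tp <- cv$truth$pairs
  for (i in seq_len(nrow(res$pairwise))) {
    e <- res$pairwise[i, ]
    k <- which(tp$src == e$src & tp$dst == e$dst)
    expect_length(k, 1)
    expect_lt(sqrt((e$tx - tp$tx[k])^2 + (e$ty - tp$ty[k])^2), 2)
  }

  # composing each tile's pairwise edge reproduces its global transform
  g <- function(id) unlist(
    comp$transforms[comp$transforms$tile_id == id, c("tx", "ty")])
  for (i in seq_len(nrow(res$pairwise))) {
    e <- res$pairwise[i, ]
    expect_equal(unname(g(e$src)), unname(c(e$tx, e$ty) + g(e$dst)),
                 tolerance = 1e-10)
  }

  # single-tile input: one component with the identity
  one <- build_montage(cv$tiles[1])
  expect_length(one$components, 1)
  expect_equal(one$components[[1]]$transforms$tx, 0)
  expect_equal(nrow(one$pairwise), 0)
  expect_error(build_montage(list()), "empty")
})

test_that("tile comparisons never cross the nominal-distance prune", {
  cv <- fx_small_grid()
  # shrink d so only rook neighbours qualify (grid step 252 px = 0.42 deg,
  # diagonal 0.59 deg)
  res <- build_montage(cv$tiles, params = montage_params(d = 0.5, seed = 2))
  pos <- data.frame(
    tile_id = names(cv$tiles),
    x = vapply(cv$tiles, function(t) t$nominal[1], 1),
    y = vapply(cv$tiles, function(t) t$nominal[2], 1))
  att <- res$stats$attempted
  for (i in seq_len(nrow(att))) {
    a <- pos[pos$tile_id == att$src[i], ]
    b <- pos[pos$tile_id == att$dst[i], ]
    expect_lte(sqrt((a$x - b$x)^2 + (a$y - b$y)^2), 0.5)
  }
})

test_that("fixed seeds reproduce the montage exactly", {
  cv <- fx_small_grid()
  r1 <- build_montage(cv$tiles, params = montage_params(seed = 11))
  r2 <- build_montage(cv$tiles, params = montage_params(seed = 11))
  expect_identical(r1$components, r2$components)
  expect_identical(r1$pairwise, r2$pairwise)
})

test_that("rendering pastes tiles into a shared canvas", {
  cv <- fx_small_grid(noise = 0)
  # single tile renders to itself
  one <- build_montage(cv$tiles[1])
  expect_identical(render_montage(cv$tiles[1], one, "confocal"),
                   cv$tiles[[1]]$modalities$confocal)

  res <- build_montage(cv$tiles, params = montage_params(seed = 3))
  canvas <- render_montage(cv$tiles, res, "confocal", 1)
  # noise-free tiles come from one scene: canvas must reproduce the source
  # region wherever tiles were painted
  sc <- generate_scene(scene_params(width = 760, height = 760,
                                    noise_sigma = 0, seed = 6))
  ref <- res$components[[1]]$reference
  off <- cv$truth$offsets
  ro <- off[off$tile_id == ref, ]
  tr <- res$components[[1]]$transforms
  x0 <- ro$ox + min(round(tr$tx)); y0 <- ro$oy + min(round(tr$ty))
  src <- sc$confocal[y0 + seq_len(nrow(canvas)), x0 + seq_len(ncol(canvas))]
  painted <- canvas > 0
  expect_gte(cor(as.numeric(canvas[painted]), as.numeric(src[painted])),
             0.999)
  expect_error(render_montage(cv$tiles, res, "nope", 1), "missing")
})
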