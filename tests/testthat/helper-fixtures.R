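# Shared fixtures, built once per test run and cached in the session.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# small clean scene for feature-level tests
fx_scene <- function() fx_get("scene", function() {
  generate_scene(scene_params(width = 600, height = 600, noise_sigma = 0,
                              seed = 1))
})

# the frozen validation fixture: 1800^2 scene, 3x3 grid of 720 px tiles,
# 30% overlap, per-tile noise sigma 5, dropout 0.1
fx_default <- function() fx_get("default", function() {
  sc <- generate_scene(scene_params(seed = 0))
  carve_tiles(sc, seed = 1)
})

fx_default_prep <- function() fx_get("default_prep", function() {
  prepare_tiles(fx_default()$tiles, seed = 0)
})

fx_default_montage <- function() fx_get("default_montage", function() {
  build_montage(fx_default_prep(), params = montage_params(seed = 0))
})

# small 2x2 grid for montage/io unit tests (360 px tiles)
fx_small_grid <- function(noise = 5) fx_get(paste0("grid_", noise), function() {
  sc <- generate_scene(scene_params(width = 760, height = 760,
                                    noise_sigma = noise, seed = 6))
  carve_tiles(sc, grid = c(2, 2), tile_size = 360, overlap_frac = 0.3,
              seed = 7)
})

# horizontally overlapping tile pair (512 px tiles, 152 px step -> 360 px
# true overlap) for the overlap-requirement sweep
fx_sweep_pair <- function(dropout) {
  fx_get(paste0("pair_", dropout), function() {
    sc <- generate_scene(scene_params(width = 680, height = 520,
                                      dropout_rate = dropout,
                                      noise_sigma = 5, seed = 0))
    cv <- carve_tiles(sc, grid = c(1, 2), tile_size = 512,
                      overlap_frac = 1 - 152 / 512, pos_jitter_px = 0,
                      seed = 1)
    tp <- cv$truth$pairs
    row <- tp[tp$src == "tile_r1c1" & tp$dst == "tile_r1c2", ]
    list(A = cv$tiles[["tile_r1c1"]], B = cv$tiles[["tile_r1c2"]],
         truth = c(row$tx, row$ty))
  })
}

# two clusters carved from one scene with zero inter-cluster overlap but
# nominally close positions (all within d = 7 degrees)
fx_two_clusters <- function() fx_get("clusters", function() {
  sc <- generate_scene(scene_params(width = 1200, height = 420,
                                    noise_sigma = 5, seed = 8))
  crop <- function(ox, id) {
    mods <- lapply(sc, function(img) img[1:360, (ox + 1):(ox + 360)])
    list(tile_id = id, nominal = c(ox / 600, 0), fov = 0.6,
         modalities = mods)
  }
  tiles <- list(crop(0, "a1"), crop(120, "a2"),
                crop(700, "b1"), crop(820, "b2"))
  names(tiles) <- vapply(tiles, `[[`, character(1), "tile_id")
  tiles
})

# exhaustive wrap-around arc-run oracle for the FAST segment test
fast_oracle <- function(patch7, lambda, eta) {
  cx <- c(0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3, -3, -3, -2, -1)
  cy <- c(-3, -3, -2, -1, 0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3)
  ctr <- patch7[4, 4]
  v <- patch7[cbind(4 + cy, 4 + cx)]
  maxrun <- function(f) {
    if (all(f)) return(16L)
    best <- 0L
    for (s in 0:15) {
      len <- 0L
      while (len < 16 && f[(s + len) %% 16 + 1]) len <- len + 1L
      best <- max(best, len)
    }
    best
  }
  run <- max(maxrun(v > ctr + lambda), maxrun(v < ctr - lambda))
  list(is_corner = run >= eta, run_length = run)
}

# round-half-away-from-zero, as the compiled descriptor rotation uses
lround <- function(x) sign(x) * floor(abs(x) + 0.5)

# the smoothed copy the detector assigns orientations on (sigma = 4)
blur_image_for_test <- function(img, sigma = 4) {
  x <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(img)),
                                           sigma = sigma)))
  pmax(pmin(x, 255), 0)
}

# fraction of rotated-image keypoints whose ratio-test match maps to the
# correct position under the known rotation
rotation_match_rate <- function(img, angle, tol = 2) {
  rot <- rotate_gray(img, angle, fill = 30)
  f0 <- detect_and_describe(img)
  f1 <- detect_and_describe(rot)
  m <- ratio_test_match(f1, f0, matcher_params(use_lsh = FALSE))
  cx <- (ncol(img) - 1) / 2
  cy <- (nrow(img) - 1) / 2
  px <- cos(angle) * (m$query_x - cx) + sin(angle) * (m$query_y - cy) + cx
  py <- -sin(angle) * (m$query_x - cx) + cos(angle) * (m$query_y - cy) + cy
  good <- sqrt((px - m$train_x)^2 + (py - m$train_y)^2) <= tol
  sum(good) / nrow(f1$keypoints)
}
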