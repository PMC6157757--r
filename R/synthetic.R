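#' Scene parameters for the synthetic photoreceptor mosaic
#'
#' The generator plants cone centres on a jittered hexagonal lattice and
#' renders them in three pixel-aligned modalities: `confocal` (Gaussian
#' reflectance spots on a dim background), `split` (signed horizontal
#' derivative of the spot field remapped around mid-grey, emulating the
#' relief look of non-confocal split detection) and `dark` (an inverted,
#' more strongly blurred spot field). Seeded cone dropout emulates
#' photoreceptor loss in pathology; additive Gaussian noise and a radial
#' vignette emulate shot noise and illumination falloff.
#'
#' @param width,height scene size in pixels.
#' @param cone_spacing centre-to-centre lattice spacing in pixels.
#' @param spacing_jitter positional jitter as a fraction of the spacing.
#' @param cone_sigma Gaussian spot width (px).
#' @param dropout_rate fraction of cones removed at random.
#' @param noise_sigma additive Gaussian noise, in intensity levels.
#' @param vignette_strength fractional intensity loss at the scene corner.
#' @param seed RNG seed; all randomness in the scene derives from it.
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(width = 1800, height = 1800, cone_spacing = 12,
                         spacing_jitter = 0.15, cone_sigma = 2.5,
                         dropout_rate = 0.1, noise_sigma = 5,
                         vignette_strength = 0.1, seed = 0) {
  stopifnot(width >= 62, height >= 62, cone_spacing > 2 * cone_sigma / 2,
            spacing_jitter >= 0, dropout_rate >= 0, dropout_rate <= 1,
            noise_sigma >= 0, vignette_strength >= 0,
            vignette_strength <= 1)
  structure(list(width = width, height = height,
                 cone_spacing = cone_spacing,
                 spacing_jitter = spacing_jitter, cone_sigma = cone_sigma,
                 dropout_rate = dropout_rate, noise_sigma = noise_sigma,
                 vignette_strength = vignette_strength,
                 seed = as.integer(seed)),
            class = "scene_params")
}

#' Generate a ground-truth photoreceptor-mosaic scene
#'
#' @param params a [scene_params()] object.
#' @return Named list of image matrices (`confocal`, `split`, `dark`), all
#'   derived from the same cone set and pixel-aligned. The planted cone
#'   centres are attached as attribute `cones` (data frame `x`, `y`,
#'   0-based scene coordinates).
#' @export
generate_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  w <- params$width; h <- params$height
  s <- params$cone_spacing
  with_seed_local(params$seed, {
    dy <- s * sqrt(3) / 2
    rows <- seq(0, h - 1, by = dy)
    centres <- do.call(rbind, lapply(seq_along(rows), function(r) {
      xs <- seq(if (r %% 2 == 0) s / 2 else 0, w - 1, by = s)
      cbind(x = xs, y = rep(rows[r], length(xs)))
    }))
    if (is.null(centres) || nrow(centres) < 3)
      stop("degenerate scene geometry", call. = FALSE)
    centres <- centres +
      matrix(rnorm(length(centres), 0, params$spacing_jitter * s),
             ncol = 2)
    keep <- runif(nrow(centres)) >= params$dropout_rate
    cones <- as.data.frame(centres[keep, , drop = FALSE])
    names(cones) <- c("x", "y")
    inb <- cones$x >= 0 & cones$x <= w - 1 & cones$y >= 0 & cones$y <= h - 1
    cones <- cones[inb, , drop = FALSE]

    # bilinear splat of unit mass at each (sub-pixel) cone centre
    delta <- matrix(0, h, w)
    x0 <- floor(cones$x); y0 <- floor(cones$y)
    fx <- cones$x - x0; fy <- cones$y - y0
    add <- function(xx, yy, wt) {
      ok <- xx >= 0 & xx < w & yy >= 0 & yy < h & wt > 0
      if (!any(ok)) return(invisible(NULL))
      idx <- yy[ok] + 1 + xx[ok] * h
      acc <- rowsum(wt[ok], idx)
      pos <- as.numeric(rownames(acc))
      delta[pos] <<- delta[pos] + acc[, 1]
      invisible(NULL)
    }
    add(x0, y0, (1 - fx) * (1 - fy))
    add(x0 + 1, y0, fx * (1 - fy))
    add(x0, y0 + 1, (1 - fx) * fy)
    add(x0 + 1, y0 + 1, fx * fy)

    blur <- function(m, sigma) {
      t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(m)),
                                          sigma = sigma)))
    }
    field <- blur(delta, params$cone_sigma)
    fmax <- max(field)
    if (fmax <= 0) fmax <- 1
    fnorm <- field / fmax

    confocal <- 30 + 200 * fnorm
    dx <- cbind(0, (field[, 3:w, drop = FALSE] -
                      field[, 1:(w - 2), drop = FALSE]) / 2, 0)
    dmax <- max(abs(dx)); if (dmax <= 0) dmax <- 1
    split_img <- 127.5 + 100 * dx / dmax
    dfield <- blur(delta, params$cone_sigma * 1.5)
    dark <- 220 - 180 * dfield / max(max(dfield), 1e-12)

    if (params$vignette_strength > 0) {
      cx <- (w - 1) / 2; cy <- (h - 1) / 2
      rad2 <- outer(((seq_len(h) - 1 - cy) / cy)^2,
                    ((seq_len(w) - 1 - cx) / cx)^2, "+") / 2
      vig <- 1 - params$vignette_strength * rad2
      confocal <- confocal * vig
      split_img <- 127.5 + (split_img - 127.5) * vig
      dark <- 220 - (220 - dark) * vig
    }
    out <- list(confocal = confocal, split = split_img, dark = dark)
    out <- lapply(out, function(m) {
      m <- round(m)
      m[m < 0] <- 0; m[m > 255] <- 255
      m
    })
    attr(out, "cones") <- cones
    attr(out, "noise_sigma") <- params$noise_sigma
    out
  })
}

#' Carve overlapping tiles from a scene with known ground truth
#'
#' Crops a regular `rows x cols` grid of square tiles with step
#' `tile_size * (1 - overlap_frac)`, plus a small seeded integer jitter on
#' the true positions. Nominal positions are the true positions converted
#' to degrees plus seeded fixation error, recorded separately from the
#' truth — exactly the situation of an imaging session where the operator
#' logs the intended fixation target while the eye wanders.
#'
#' Acquisition noise is independent between tiles, so each carved tile gets
#' its own seeded additive Gaussian noise (the scene itself is rendered
#' noise-free); overlapping tiles therefore agree on structure but not on
#' noise, as real repeated acquisitions do.
#'
#' @param scene output of [generate_scene()].
#' @param grid integer `c(rows, cols)`.
#' @param tile_size tile side in pixels.
#' @param overlap_frac nominal fractional overlap between grid neighbours.
#' @param fixation_jitter_deg s.d. of the nominal-position error (degrees).
#' @param px_per_deg pixel scale (pixels per degree of visual angle).
#' @param pos_jitter_px max absolute integer jitter on true tile origins.
#' @param noise_sigma per-tile additive noise s.d.; defaults to the scene's
#'   `noise_sigma` parameter.
#' @param seed RNG seed.
#' @return List with `tiles` (each: `tile_id`, `nominal` degrees, `fov`,
#'   `modalities`), and `truth`: per-tile true scene offsets (px) plus the
#'   pairwise data frame of true relative translations `tx, ty` (mapping
#'   `src` pixels into `dst`'s frame) for every pair with positive overlap
#'   area.
#' @export
carve_tiles <- function(scene, grid = c(3, 3), tile_size = 720,
                        overlap_frac = 0.3, fixation_jitter_deg = 0.05,
                        px_per_deg = 600, pos_jitter_px = 2,
                        noise_sigma = NULL, seed = 0) {
  if (is.null(noise_sigma))
    noise_sigma <- attr(scene, "noise_sigma") %||% 0
  h <- nrow(scene[[1]]); w <- ncol(scene[[1]])
  step <- round(tile_size * (1 - overlap_frac))
  if ((grid[2] - 1) * step + tile_size > w ||
      (grid[1] - 1) * step + tile_size > h)
    stop("tile grid does not fit in the scene", call. = FALSE)
  with_seed_local(seed, {
    tiles <- list()
    offs <- list()
    for (r in seq_len(grid[1])) for (c in seq_len(grid[2])) {
      jx <- sample(-pos_jitter_px:pos_jitter_px, 1)
      jy <- sample(-pos_jitter_px:pos_jitter_px, 1)
      ox <- (c - 1) * step + jx
      oy <- (r - 1) * step + jy
      ox <- max(0, min(ox, w - tile_size))
      oy <- max(0, min(oy, h - tile_size))
      if (ox + tile_size > w || oy + tile_size > h)
        stop("tile grid does not fit in the scene", call. = FALSE)
      id <- sprintf("tile_r%dc%d", r, c)
      nominal <- c(ox, oy) / px_per_deg +
        rnorm(2, 0, fixation_jitter_deg)
      mods <- lapply(scene, function(img) {
        m <- img[(oy + 1):(oy + tile_size), (ox + 1):(ox + tile_size),
                 drop = FALSE]
        if (noise_sigma > 0) {
          m <- round(m + matrix(rnorm(length(m), 0, noise_sigma),
                                nrow(m), ncol(m)))
          m[m < 0] <- 0; m[m > 255] <- 255
        }
        m
      })
      tiles[[id]] <- list(tile_id = id, nominal = nominal,
                          fov = tile_size / px_per_deg,
                          modalities = mods)
      offs[[id]] <- c(ox, oy)
    }
    ids <- names(tiles)
    pairs <- list()
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (i == j) next
      oi <- offs[[ids[i]]]; oj <- offs[[ids[j]]]
      ovx <- tile_size - abs(oi[1] - oj[1])
      ovy <- tile_size - abs(oi[2] - oj[2])
      if (ovx <= 0 || ovy <= 0) next
      pairs[[length(pairs) + 1]] <- data.frame(
        src = ids[i], dst = ids[j],
        tx = oi[1] - oj[1], ty = oi[2] - oj[2],
        overlap_px = min(ovx, ovy))
    }
    truth <- list(
      offsets = data.frame(
        tile_id = ids,
        ox = vapply(offs, `[`, numeric(1), 1),
        oy = vapply(offs, `[`, numeric(1), 2),
        row.names = NULL),
      pairs = if (length(pairs)) do.call(rbind, pairs)
              else data.frame(src = character(0), dst = character(0),
                              tx = numeric(0), ty = numeric(0),
                              overlap_px = numeric(0)))
    list(tiles = tiles, truth = truth)
  })
}

#' Write the default ground-truth fixture to disk
#'
#' Generates the frozen validation fixture — an 1800x1800 scene with 12 px
#' cone spacing carved into a 3x3 grid of 720 px tiles at 30% nominal
#' overlap — and writes per-tile TIFF images (three modalities), a
#' `manifest.csv` understood by [read_tileset()], and a `truth.json` with
#' the true offsets and pairwise translations.
#'
#' @param out_dir writable output directory (created if missing).
#' @param seed RNG seed controlling the whole fixture.
#' @param noise_sigma,dropout_rate scene difficulty settings.
#' @return Path of the written manifest, invisibly; attribute `truth`
#'   carries the in-memory ground truth.
#' @export
default_fixture <- function(out_dir, seed = 0, noise_sigma = 5,
                            dropout_rate = 0.1) {
  scene <- generate_scene(scene_params(noise_sigma = noise_sigma,
                                       dropout_rate = dropout_rate,
                                       seed = seed))
  carved <- carve_tiles(scene, seed = derive_seed(seed, 1))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(carved$tiles, function(tile) {
    paths <- vapply(names(tile$modalities), function(mod) {
      p <- file.path(out_dir, paste0(tile$tile_id, "_", mod, ".tif"))
      tiff::writeTIFF(tile$modalities[[mod]] / 255, p)
      basename(p)
    }, character(1))
    data.frame(tile_id = tile$tile_id,
               nominal_x_deg = tile$nominal[1],
               nominal_y_deg = tile$nominal[2],
               fov_deg = tile$fov,
               confocal_path = paths[["confocal"]],
               split_path = paths[["split"]],
               dark_path = paths[["dark"]])
  })
  manifest <- file.path(out_dir, "manifest.csv")
  write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  jsonlite::write_json(
    list(offsets = carved$truth$offsets, pairs = carved$truth$pairs),
    file.path(out_dir, "truth.json"),
    dataframe = "rows", digits = NA)
  structure(invisible(manifest), truth = carved$truth)
}

#' Rotate a grayscale image about its centre
#'
#' Inverse-mapped bilinear rotation keeping the input dimensions; samples
#' falling outside the source are filled with `fill`. Used by the
#' rotation-robustness harness: a keypoint at `p` in the source appears at
#' `R(angle) (p - c) + c` in the output.
#'
#' @param image image matrix.
#' @param angle rotation in radians (from +x toward +y, i.e. clockwise on
#'   screen).
#' @param fill background fill value.
#' @return Rotated image matrix of the same size.
#' @export
rotate_gray <- function(image, angle, fill = 0) {
  h <- nrow(image); w <- ncol(image)
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  co <- cos(angle); si <- sin(angle)
  xg <- matrix(rep(0:(w - 1), each = h), h, w) - cx
  yg <- matrix(rep(0:(h - 1), times = w), h, w) - cy
  # inverse map: source = R(-angle) (target - c) + c
  sx <- co * xg + si * yg + cx
  sy <- -si * xg + co * yg + cy
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  val <- function(xx, yy) {
    v <- matrix(fill, h, w)
    ok <- xx >= 0 & xx < w & yy >= 0 & yy < h
    v[ok] <- image[cbind(yy[ok] + 1, xx[ok] + 1)]
    v
  }
  out <- val(x0, y0) * (1 - fx) * (1 - fy) +
    val(x0 + 1, y0) * fx * (1 - fy) +
    val(x0, y0 + 1) * (1 - fx) * fy +
    val(x0 + 1, y0 + 1) * fx * fy
  out <- round(out)
  out[out < 0] <- 0; out[out > 255] <- 255
  out
}
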