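#' Read a tile set from a manifest
#'
#' The manifest is a delimited text file (comma-separated, with a header)
#' whose rows describe one tile each: `tile_id`, `nominal_x_deg`,
#' `nominal_y_deg`, `fov_deg`, `confocal_path` and, optionally,
#' `split_path` and `dark_path`. Image paths are resolved relative to the
#' manifest's directory; grayscale TIFF and PNG are accepted. Colour
#' images are converted to grayscale by luminance, and inputs deeper than
#' 8 bits are rescaled to 8 bits with a warning. The modalities of each
#' tile must share dimensions (they are acquired in spatial registration).
#'
#' @param manifest_path path to the manifest file.
#' @return Named list of tiles (`tile_id`, `nominal`, `fov`, `modalities`).
#' @export
read_tileset <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path, call. = FALSE)
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("tile_id", "nominal_x_deg", "nominal_y_deg", "confocal_path")
  if (nrow(man) == 0 || !all(need %in% names(man)))
    stop("manifest has no parsable rows (need columns ",
         paste(need, collapse = ", "), ")", call. = FALSE)
  if (anyDuplicated(man$tile_id))
    stop("duplicate tile_id in manifest: ",
         man$tile_id[duplicated(man$tile_id)][1], call. = FALSE)
  base <- dirname(normalizePath(manifest_path))
  path_cols <- c(confocal = "confocal_path", split = "split_path",
                 dark = "dark_path")
  tiles <- list()
  for (i in seq_len(nrow(man))) {
    id <- as.character(man$tile_id[i])
    mods <- list()
    for (mod in names(path_cols)) {
      col <- path_cols[[mod]]
      if (!col %in% names(man)) next
      p <- man[[col]][i]
      if (is.na(p) || !nzchar(p)) next
      full <- if (file.exists(p)) p else file.path(base, p)
      if (!file.exists(full))
        stop("tile ", id, ": image file not found: ", p, call. = FALSE)
      mods[[mod]] <- load_gray(full)
    }
    if (length(mods) == 0)
      stop("tile ", id, ": no modality images", call. = FALSE)
    dims <- vapply(mods, dim, numeric(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("tile ", id, ": modality images differ in size", call. = FALSE)
    fov <- if ("fov_deg" %in% names(man)) man$fov_deg[i] else NA_real_
    tiles[[id]] <- list(
      tile_id = id,
      nominal = c(man$nominal_x_deg[i], man$nominal_y_deg[i]),
      fov = fov, modalities = mods)
  }
  tiles
}

# Load one grayscale raster as an 8-bit intensity matrix (rows = y).
load_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = , tiff = tiff::readTIFF(path, as.is = TRUE),
                png = {
                  x <- png::readPNG(path)
                  if (max(x) <= 1) x * 255 else x
                },
                stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(img)) == 3) {
    nch <- dim(img)[3]
    img <- if (nch >= 3)
      0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    else img[, , 1]
  }
  if (max(img) > 255) {
    warning("rescaling >8-bit image to 8 bits: ", basename(path))
    img <- img / (max(img) / 255)
  }
  img <- round(img)
  img[img < 0] <- 0; img[img > 255] <- 255
  img
}

#' Write montage outputs
#'
#' Writes `transforms.json` (per component: reference tile, per-tile global
#' translations in pixels; plus the accepted pairwise edges with inlier
#' counts and the run parameters), a plain-text run log, and — when
#' `render` is set — one grayscale TIFF per component and modality.
#'
#' @param result a `montage_result`.
#' @param tiles tile list (or [prepare_tiles()] output); needed for
#'   rendering.
#' @param out_dir output directory (created if missing).
#' @param render write montage canvases.
#' @param params,ransac,matcher parameter objects recorded in the JSON.
#' @return Character vector of written paths, invisibly.
#' @export
write_outputs <- function(result, tiles, out_dir, render = FALSE,
                          params = montage_params(),
                          ransac = ransac_params(),
                          matcher = matcher_params()) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  payload <- list(
    components = lapply(result$components, function(cp) list(
      reference = cp$reference,
      transforms = cp$transforms)),
    pairwise = result$pairwise,
    parameters = list(T1 = params$T1, T2 = params$T2, d = params$d,
                      seed = params$seed,
                      ransac_iterations = ransac$iterations,
                      delta = ransac$delta, ratio = matcher$ratio,
                      lsh_tables = matcher$b,
                      lsh_key_bits = matcher$key_bits,
                      use_lsh = matcher$use_lsh))
  jpath <- file.path(out_dir, "transforms.json")
  jsonlite::write_json(payload, jpath, dataframe = "rows",
                       auto_unbox = TRUE, digits = 8, pretty = TRUE)
  paths <- jpath
  log_path <- file.path(out_dir, "run_log.txt")
  lines <- c(
    sprintf("tiles: %d", sum(vapply(result$components,
                                    function(cp) length(cp$tile_ids), 1L))),
    sprintf("components: %d", length(result$components)),
    sprintf("component sizes: %s",
            paste(vapply(result$components,
                         function(cp) length(cp$tile_ids), 1L),
                  collapse = ", ")),
    sprintf("seed: %d  T1: %g  T2: %g  d: %g  delta: %g  ratio: %g",
            params$seed, params$T1, params$T2, params$d, ransac$delta,
            matcher$ratio),
    "accepted edges (src -> dst : inliers):",
    if (nrow(result$pairwise))
      sprintf("  %s -> %s : %d", result$pairwise$src, result$pairwise$dst,
              result$pairwise$inliers)
    else "  (none)")
  writeLines(lines, log_path)
  paths <- c(paths, log_path)
  if (render) {
    get_tile <- function(id) {
      t <- tiles[[id]]
      if (!is.null(t$features)) t$tile else t
    }
    for (ci in seq_along(result$components)) {
      comp <- result$components[[ci]]
      mods <- Reduce(intersect, lapply(comp$tile_ids, function(id)
        names(get_tile(id)$modalities)))
      for (mod in mods) {
        canvas <- render_montage(tiles, result, mod, ci)
        p <- file.path(out_dir,
                       sprintf("montage_c%02d_%s.tif", ci, mod))
        tiff::writeTIFF(canvas / 255, p)
        paths <- c(paths, p)
      }
    }
  }
  invisible(paths)
}
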