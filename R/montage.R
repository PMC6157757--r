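#' Nominal-position adjacency
#'
#' Tiles are compared only when the Euclidean distance between their
#' recorded (nominal) acquisition positions is at most `d`. Fixation targets
#' are recorded in degrees of visual angle, so `d` defaults to degrees;
#' positions in other units work as long as `d` matches.
#'
#' @param positions data frame with `tile_id`, `x`, `y`.
#' @param d nominally-close distance.
#' @return Named list: for each tile id, the character vector of its
#'   nominally close tile ids (symmetric, irreflexive).
#' @export
nominally_close <- function(positions, d = 7) {
  stopifnot(all(c("tile_id", "x", "y") %in% names(positions)),
            all(is.finite(positions$x)), all(is.finite(positions$y)))
  ids <- as.character(positions$tile_id)
  n <- length(ids)
  adj <- stats::setNames(vector("list", n), ids)
  if (n == 0) return(adj)
  dx <- outer(positions$x, positions$x, "-")
  dy <- outer(positions$y, positions$y, "-")
  close <- sqrt(dx^2 + dy^2) <= d
  diag(close) <- FALSE
  for (i in seq_len(n)) adj[[i]] <- ids[close[i, ]]
  adj
}

#' Precompute features and LSH indexes for a tile set
#'
#' Detects keypoints and descriptors once per tile and modality, and builds
#' one LSH index per modality so repeated matching against the same tile
#' reuses its hash tables. This mirrors the montage algorithm's single
#' up-front feature pass over all tiles.
#'
#' @param tiles list of tiles as returned by [read_tileset()] or
#'   [carve_tiles()].
#' @param detector a [detector_params()] object.
#' @param matcher a [matcher_params()] object.
#' @param pattern binary test pattern.
#' @param seed base seed for per-index LSH bit sampling.
#' @return Named list (by tile id) of lists: `tile`, `features` (per
#'   modality: `keypoints`, `descriptors`, `lsh`).
#' @export
prepare_tiles <- function(tiles, detector = detector_params(),
                          matcher = matcher_params(),
                          pattern = brief_pattern(), seed = 0) {
  stopifnot(length(tiles) >= 1)
  out <- vector("list", length(tiles))
  names(out) <- vapply(tiles, function(t) t$tile_id, character(1))
  k <- 0L
  for (i in seq_along(tiles)) {
    tile <- tiles[[i]]
    feats <- list()
    for (mod in names(tile$modalities)) {
      k <- k + 1L
      fd <- detect_and_describe(tile$modalities[[mod]], detector, pattern)
      fd$lsh <- if (ncol(fd$descriptors) > 0 && matcher$use_lsh)
        build_lsh_index(fd$descriptors, matcher, seed = derive_seed(seed, k))
      else NULL
      feats[[mod]] <- fd
    }
    out[[i]] <- list(tile = tile, features = feats)
  }
  out
}

#' Align one tile against an ordered list of montage candidates
#'
#' Iterates over the candidate destination tiles in the given order. Each
#' candidate is matched ([match_tiles()]) and aligned ([ransac_align()]);
#' an alignment whose consensus inlier count exceeds `T1` is accepted
#' immediately and the remaining candidates are never evaluated ("good
#' enough"). Otherwise, after all candidates are exhausted, the best-seen
#' alignment is accepted if its count exceeds `T2`.
#'
#' @param src_id tile id to align.
#' @param candidate_ids candidate destination tile ids, in evaluation order.
#' @param prepared output of [prepare_tiles()].
#' @param params a [montage_params()] object.
#' @param ransac a [ransac_params()] object.
#' @param matcher a [matcher_params()] object.
#' @param probe optional environment; if given, counters `n_ransac` and
#'   `n_match` are incremented per candidate evaluation.
#' @param best_search if `TRUE`, ignore the `T1` early exit and always take
#'   the best candidate (the exhaustive strategy this package's greedy rule
#'   is measured against).
#' @return `NULL` if no candidate passes, else a list with `dst_id`,
#'   `transform` and `n_evaluated`.
#' @export
align_to_montage <- function(src_id, candidate_ids, prepared,
                             params = montage_params(),
                             ransac = ransac_params(),
                             matcher = matcher_params(),
                             probe = NULL, best_search = FALSE) {
  best <- NULL
  n_eval <- 0L
  for (dst_id in candidate_ids) {
    m <- tryCatch(
      match_tiles(prepared[[src_id]]$features, prepared[[dst_id]]$features,
                  matcher),
      error = function(e) NULL)
    n_eval <- n_eval + 1L
    if (!is.null(probe)) {
      probe$n_match <- (probe$n_match %||% 0L) + 1L
      probe$n_ransac <- (probe$n_ransac %||% 0L) + 1L
      probe$pairs[[length(probe$pairs) + 1L]] <-
        data.frame(src = src_id, dst = dst_id)
    }
    tr <- if (is.null(m) || nrow(m) == 0) NULL else ransac_align(m, ransac)
    if (is.null(tr)) next
    if (!best_search && tr$consensus_count > params$T1)
      return(list(dst_id = dst_id, transform = tr, n_evaluated = n_eval))
    if (is.null(best) || tr$consensus_count > best$transform$consensus_count)
      best <- list(dst_id = dst_id, transform = tr)
  }
  if (!is.null(best) && best$transform$consensus_count > params$T2) {
    best$n_evaluated <- n_eval
    return(best)
  }
  NULL
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Grow montages from random tiles of reference
#'
#' Implements the iterative montage framework: seed a component with a
#' random unaligned tile (the tile of reference, global transform zero),
#' then repeatedly sweep the unaligned tiles, attempting to align each
#' against the aligned, nominally close tiles of the current component
#' (nearest nominal position first). When a full sweep aligns nothing the
#' component is closed and a new tile of reference is drawn; the loop ends
#' when no unaligned tiles remain. Disjoint retinal regions therefore come
#' out as separate components.
#'
#' @param tiles list of tiles, or the result of [prepare_tiles()] (detected
#'   features are then reused as-is).
#' @param params a [montage_params()] object.
#' @param ransac a [ransac_params()] object.
#' @param matcher a [matcher_params()] object.
#' @param detector a [detector_params()] object (used only when `tiles` are
#'   raw tiles).
#' @param pattern binary test pattern.
#' @param best_search if `TRUE`, disable the good-enough early exit.
#' @return A `montage_result` list: `components` (each with `reference`,
#'   `tile_ids` in alignment order, and a `transforms` data frame of global
#'   per-tile translations in pixels), `pairwise` (accepted edges with
#'   inlier counts), and `stats` (counters: `n_ransac`, `n_match`,
#'   `attempted` pair table).
#' @export
build_montage <- function(tiles, params = montage_params(),
                          ransac = ransac_params(),
                          matcher = matcher_params(),
                          detector = detector_params(),
                          pattern = brief_pattern(),
                          best_search = FALSE) {
  if (length(tiles) == 0) stop("empty tile list", call. = FALSE)
  prepared <- if (!is.null(tiles[[1]]$features)) tiles
              else prepare_tiles(tiles, detector, matcher, pattern,
                                 seed = params$seed)
  ids <- names(prepared)
  pos <- data.frame(
    tile_id = ids,
    x = vapply(prepared, function(p) p$tile$nominal[1], numeric(1)),
    y = vapply(prepared, function(p) p$tile$nominal[2], numeric(1)))
  adj <- nominally_close(pos, params$d)
  probe <- new.env(parent = emptyenv())
  probe$n_match <- 0L
  probe$n_ransac <- 0L
  probe$pairs <- list()

  unaligned <- ids
  components <- list()
  pairwise <- list()
  global <- stats::setNames(vector("list", length(ids)), ids)

  with_seed_local(params$seed, {
    while (length(unaligned) > 0) {
      tof <- if (length(unaligned) == 1) unaligned
             else sample(unaligned, 1)
      unaligned <- setdiff(unaligned, tof)
      comp_ids <- tof
      global[[tof]] <- c(0, 0)
      progress <- TRUE
      while (progress && length(unaligned) > 0) {
        progress <- FALSE
        sweep <- if (length(unaligned) == 1) unaligned
                 else sample(unaligned)
        for (src in sweep) {
          cand <- intersect(adj[[src]], comp_ids)
          if (length(cand) == 0) next
          # nearest nominal position first; ties by tile id
          dists <- sqrt((pos$x[match(cand, pos$tile_id)] -
                           pos$x[match(src, pos$tile_id)])^2 +
                        (pos$y[match(cand, pos$tile_id)] -
                           pos$y[match(src, pos$tile_id)])^2)
          cand <- cand[order(dists, cand)]
          res <- align_to_montage(src, cand, prepared, params, ransac,
                                  matcher, probe = probe,
                                  best_search = best_search)
          if (is.null(res)) next
          tr <- res$transform
          global[[src]] <- c(tr$tx, tr$ty) + global[[res$dst_id]]
          comp_ids <- c(comp_ids, src)
          unaligned <- setdiff(unaligned, src)
          pairwise[[length(pairwise) + 1]] <- data.frame(
            src = src, dst = res$dst_id, tx = tr$tx, ty = tr$ty,
            inliers = tr$consensus_count)
          progress <- TRUE
        }
      }
      components[[length(components) + 1]] <- list(
        reference = tof,
        tile_ids = comp_ids,
        transforms = data.frame(
          tile_id = comp_ids,
          tx = vapply(comp_ids, function(i) global[[i]][1], numeric(1)),
          ty = vapply(comp_ids, function(i) global[[i]][2], numeric(1)),
          row.names = NULL))
    }
  })
  structure(list(
    components = components,
    pairwise = if (length(pairwise)) do.call(rbind, pairwise)
               else data.frame(src = character(0), dst = character(0),
                               tx = numeric(0), ty = numeric(0),
                               inliers = integer(0)),
    stats = list(n_ransac = probe$n_ransac, n_match = probe$n_match,
                 attempted = if (length(probe$pairs))
                   do.call(rbind, probe$pairs)
                 else data.frame(src = character(0), dst = character(0)))),
    class = "montage_result")
}

#' Render one montage component to a canvas
#'
#' Paints the tiles of a component onto a canvas sized to the bounding box
#' of their transformed extents, in alignment order; overlapping pixels are
#' resolved last-painted-wins. Transforms are rounded to the pixel grid for
#' painting. The render is an inspection artifact; quality metrics are
#' computed on pairwise overlaps, not on this canvas.
#'
#' @param tiles list of tiles (or [prepare_tiles()] output).
#' @param result a `montage_result`.
#' @param modality modality to render; must be present in all component
#'   tiles.
#' @param component_index which component.
#' @return Image matrix (background 0).
#' @export
render_montage <- function(tiles, result, modality = "confocal",
                           component_index = 1) {
  comp <- result$components[[component_index]]
  get_tile <- function(id) {
    t <- tiles[[id]]
    if (!is.null(t$features)) t$tile else t
  }
  for (id in comp$tile_ids)
    if (!modality %in% names(get_tile(id)$modalities))
      stop("modality '", modality, "' missing in tile ", id, call. = FALSE)
  tr <- comp$transforms
  first <- get_tile(comp$tile_ids[1])$modalities[[modality]]
  # global transform maps a tile's pixels into the reference frame
  ox <- round(tr$tx); oy <- round(tr$ty)
  sizes <- vapply(comp$tile_ids, function(id) {
    dim(get_tile(id)$modalities[[modality]])
  }, numeric(2))
  x0 <- min(ox); y0 <- min(oy)
  x1 <- max(ox + sizes[2, ]); y1 <- max(oy + sizes[1, ])
  canvas <- matrix(0, y1 - y0, x1 - x0)
  for (i in seq_along(comp$tile_ids)) {
    img <- get_tile(comp$tile_ids[i])$modalities[[modality]]
    rr <- (oy[i] - y0) + seq_len(nrow(img))
    cc <- (ox[i] - x0) + seq_len(ncol(img))
    canvas[rr, cc] <- img
  }
  canvas
}
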