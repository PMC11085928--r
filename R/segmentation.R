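## Per-layer nucleus segmentation: deterministic classical path
## (threshold -> fill holes -> optional watershed split -> area filter),
## tiling of large layers with label-merge across overlaps, and IOU/dice.

#' Segmentation configuration
#'
#' @param method \code{"classical"} (default, deterministic) or \code{"cnn"}
#'   (a trained model from \code{\link{train_segmenter}} passed via
#'   \code{model}).
#' @param intensity_threshold \code{"otsu"} or a fixed numeric threshold in
#'   [0, 1].
#' @param min_area_px,max_area_px area filter bounds in pixels. The defaults
#'   bracket the synthetic nucleus size range (full axes 7-18 um at
#'   0.5 um/px give areas of roughly 250-1000 px; defocused appearances above
#'   the intensity threshold are smaller, hence the low floor).
#' @param watershed_split split touching blobs by distance-map watershed.
#' @param tile_size_px tile edge for large layers (>= 64).
#' @param tile_overlap_px overlap strip between tiles, used to merge objects
#'   that straddle tile borders.
#' @param model optional trained segmenter for \code{method = "cnn"}.
#' @param prob_threshold probability cut for the trained segmenter.
#' @return An object of class \code{seg_config}.
#' @export
seg_config <- function(method = c("classical", "cnn"),
                       intensity_threshold = "otsu",
                       min_area_px = 64L,
                       max_area_px = 50000L,
                       watershed_split = TRUE,
                       tile_size_px = 1024L,
                       tile_overlap_px = 64L,
                       model = NULL,
                       prob_threshold = 0.5) {
  method <- match.arg(method)
  if (min_area_px >= max_area_px) stop("min_area_px must be < max_area_px")
  if (tile_size_px < 64L) stop("tile_size_px must be >= 64")
  if (tile_overlap_px >= tile_size_px) stop("tile overlap must be < tile size")
  if (method == "cnn" && is.null(model))
    stop("method 'cnn' requires a trained model (see train_segmenter)")
  structure(list(method = method, intensity_threshold = intensity_threshold,
                 min_area_px = as.integer(min_area_px),
                 max_area_px = as.integer(max_area_px),
                 watershed_split = isTRUE(watershed_split),
                 tile_size_px = as.integer(tile_size_px),
                 tile_overlap_px = as.integer(tile_overlap_px),
                 model = model, prob_threshold = prob_threshold),
            class = "seg_config")
}

config_provenance <- function(config) {
  flat <- config[setdiff(names(config), "model")]
  paste0(config$method, ":",
         paste(names(flat), vapply(flat, function(v) paste(format(v), collapse = ","),
                                   ""), sep = "=", collapse = ";"))
}

#' Split an image into overlapping tiles
#'
#' Tiles are laid on a grid with stride \code{tile_size_px - overlap_px};
#' border tiles are zero-padded up to the full tile size and the padded region
#' is flagged so reassembly can crop it away.
#'
#' @param image matrix.
#' @param tile_size_px tile edge (px).
#' @param overlap_px overlap between neighbouring tiles (px, < tile size).
#' @return List of tiles, each a list with \code{tile} (matrix
#'   \code{tile_size_px} square), \code{offset} (0-based \code{c(x, y)} of the
#'   tile origin in the source), and \code{valid} (\code{c(w, h)} of the
#'   unpadded region).
#' @export
tile_image <- function(image, tile_size_px, overlap_px = 0L) {
  if (tile_size_px <= overlap_px) stop("tile_size_px must exceed overlap_px")
  W <- nrow(image); H <- ncol(image)
  stride <- tile_size_px - overlap_px
  starts <- function(n) {
    s <- seq(1L, max(1L, n - overlap_px), by = stride)
    # drop starts that add no new coverage
    s[s == 1L | s + overlap_px <= n]
  }
  out <- list()
  for (sy in starts(H)) for (sx in starts(W)) {
    w <- min(tile_size_px, W - sx + 1L)
    h <- min(tile_size_px, H - sy + 1L)
    tile <- matrix(0, tile_size_px, tile_size_px)
    tile[seq_len(w), seq_len(h)] <- image[sx:(sx + w - 1L), sy:(sy + h - 1L)]
    out[[length(out) + 1L]] <- list(tile = tile,
                                    offset = c(x = sx - 1L, y = sy - 1L),
                                    valid = c(w = w, h = h))
  }
  out
}

#' Reassemble tiles into the original image
#'
#' Inverse of \code{\link{tile_image}}: writes each tile's unpadded region
#' back at its offset (later tiles overwrite overlap strips with identical
#' content).
#'
#' @param tiles list from \code{\link{tile_image}}.
#' @param dim \code{c(width, height)} of the original image.
#' @return The reassembled matrix.
#' @export
stitch_tiles <- function(tiles, dim) {
  img <- matrix(0, dim[1], dim[2])
  for (t in tiles) {
    w <- t$valid["w"]; h <- t$valid["h"]
    img[(t$offset["x"] + 1):(t$offset["x"] + w),
        (t$offset["y"] + 1):(t$offset["y"] + h)] <- t$tile[seq_len(w), seq_len(h)]
  }
  img
}

#' Segment nuclei in one layer
#'
#' Classical deterministic path: intensity threshold (Otsu or fixed), hole
#' filling, optional watershed split of touching blobs on the distance map,
#' then an area filter keeping objects in
#' \code{[min_area_px, max_area_px]}. With \code{method = "cnn"} the
#' probability map of the trained segmenter replaces the raw intensities
#' before thresholding at \code{prob_threshold}; the rest of the path is
#' unchanged. Labels are renumbered consecutively from 1.
#'
#' @param image single-channel matrix with intensities in [0, 1].
#' @param config a \code{\link{seg_config}}.
#' @param layer_index 0-based layer index recorded on the mask.
#' @return An object of class \code{layer_mask}: list with \code{labels}
#'   (integer matrix, 0 = background), \code{layer_index}, \code{n_objects},
#'   and \code{provenance}.
#' @export
segment_layer <- function(image, config = seg_config(), layer_index = 0L) {
  stopifnot(is.matrix(image))
  if (config$method == "cnn") {
    image <- predict_segmenter(config$model, image)
    thr <- config$prob_threshold
  } else if (identical(config$intensity_threshold, "otsu")) {
    rng <- range(image)
    thr <- if (diff(rng) < 1e-8) Inf  # blank layer: nothing above threshold
           else EBImage::otsu(EBImage::Image(image), range = c(0, 1))
  } else {
    thr <- config$intensity_threshold
  }
  bw <- image > thr
  if (!any(bw)) {
    labels <- matrix(0L, nrow(image), ncol(image))
    return(new_layer_mask(labels, layer_index, config))
  }
  bw <- EBImage::fillHull(EBImage::Image(bw))
  if (config$watershed_split) {
    dm <- EBImage::distmap(bw)
    lab <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  } else {
    lab <- EBImage::bwlabel(bw)
  }
  labels <- EBImage::imageData(lab)
  storage.mode(labels) <- "integer"
  labels <- filter_by_area(labels, config$min_area_px, config$max_area_px)
  new_layer_mask(labels, layer_index, config)
}

new_layer_mask <- function(labels, layer_index, config) {
  structure(list(labels = labels,
                 layer_index = as.integer(layer_index),
                 n_objects = max(labels),
                 provenance = config_provenance(config)),
            class = "layer_mask")
}

#' @export
print.layer_mask <- function(x, ...) {
  cat(sprintf("layer_mask: layer %d, %d objects, %s\n",
              x$layer_index, x$n_objects, x$provenance))
  invisible(x)
}

## Drops labels outside [min_area, max_area] and renumbers the rest 1..K.
filter_by_area <- function(labels, min_area, max_area) {
  if (max(labels) == 0L) return(labels)
  sizes <- tabulate(labels[labels > 0L], nbins = max(labels))
  keep <- which(sizes >= min_area & sizes <= max_area)
  remap <- integer(max(labels))
  remap[keep] <- seq_along(keep)
  out <- labels
  pos <- labels > 0L
  out[pos] <- remap[labels[pos]]
  out
}

#' Segment a large layer tile by tile
#'
#' Segments each tile independently and merges objects across tile borders by
#' label equivalence over the overlap strips: two tile-level objects that
#' share any pixel are the same nucleus. For objects not touching tile
#' borders the result matches whole-image segmentation.
#'
#' @inheritParams segment_layer
#' @return A \code{layer_mask} covering the full layer.
#' @export
segment_layer_tiled <- function(image, config = seg_config(), layer_index = 0L) {
  W <- nrow(image); H <- ncol(image)
  if (W <= config$tile_size_px && H <= config$tile_size_px)
    return(segment_layer(image, config, layer_index))
  # the threshold must not depend on the tiling: resolve Otsu on the whole
  # layer once, so empty tiles do not threshold their own noise
  if (config$method == "classical" &&
      identical(config$intensity_threshold, "otsu")) {
    config$intensity_threshold <- if (diff(range(image)) < 1e-8) Inf
      else EBImage::otsu(EBImage::Image(image), range = c(0, 1))
  }
  tiles <- tile_image(image, config$tile_size_px, config$tile_overlap_px)
  canvas <- matrix(0L, W, H)
  parent <- integer(0)  # union-find over global labels
  find_root <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  next_label <- 0L
  for (t in tiles) {
    m <- segment_layer(t$tile, config, layer_index)$labels
    w <- t$valid["w"]; h <- t$valid["h"]
    m <- m[seq_len(w), seq_len(h), drop = FALSE]
    if (max(m) == 0L) next
    glob <- integer(max(m))
    for (loc in seq_len(max(m))) { next_label <- next_label + 1L
                                   parent[next_label] <- next_label
                                   glob[loc] <- next_label }
    xs <- (t$offset["x"] + 1):(t$offset["x"] + w)
    ys <- (t$offset["y"] + 1):(t$offset["y"] + h)
    sub <- canvas[xs, ys, drop = FALSE]
    both <- sub > 0L & m > 0L
    if (any(both)) {
      pairs <- unique(cbind(sub[both], glob[m[both]]))
      for (r in seq_len(nrow(pairs))) {
        ra <- find_root(pairs[r, 1]); rb <- find_root(pairs[r, 2])
        if (ra != rb) parent[rb] <- ra
      }
    }
    write_pos <- m > 0L & sub == 0L
    sub[write_pos] <- glob[m[write_pos]]
    canvas[xs, ys] <- sub
  }
  if (next_label > 0L) {
    roots <- vapply(seq_len(next_label), find_root, 0L)
    final <- integer(next_label)
    final[] <- match(roots, unique(roots))
    pos <- canvas > 0L
    canvas[pos] <- final[canvas[pos]]
    # renumber consecutively (some roots may have lost all pixels to overlaps)
    present <- sort(unique(canvas[pos]))
    remap <- integer(max(present))
    remap[present] <- seq_along(present)
    canvas[pos] <- remap[canvas[pos]]
  }
  new_layer_mask(canvas, layer_index, config)
}

#' Segment every layer of a stack with one consistent threshold
#'
#' Cross-layer deduplication compares patches between layers, which requires
#' the layers to be segmented consistently: with
#' \code{intensity_threshold = "otsu"} the Otsu threshold is computed once on
#' the pooled intensities of the whole stack and applied to every layer
#' (a z-stack is one acquisition with one intensity scale), rather than
#' per layer, where sparsely populated layers would get erratic thresholds
#' that truncate dim defocused appearances. Layers larger than the configured
#' tile size are segmented tile by tile.
#'
#' @param stack a \code{nuc_stack}.
#' @param config a \code{\link{seg_config}}.
#' @return List of \code{layer_mask}, one per layer.
#' @export
segment_stack <- function(stack, config = seg_config()) {
  stopifnot(inherits(stack, "nuc_stack"))
  cfg <- config
  if (cfg$method == "classical" && identical(cfg$intensity_threshold, "otsu")) {
    pooled <- matrix(unlist(stack$layers, use.names = FALSE), ncol = 1)
    if (diff(range(pooled)) < 1e-8) {
      cfg$intensity_threshold <- Inf  # blank stack
    } else {
      cfg$intensity_threshold <-
        EBImage::otsu(EBImage::Image(pooled), range = c(0, 1))
    }
  }
  lapply(seq_along(stack$layers) - 1L, function(l)
    segment_layer_tiled(stack$layers[[l + 1L]], cfg, l))
}

#' Intersection-over-union and dice overlap between two binary masks
#'
#' \code{iou = |A n B| / |A u B|} and \code{dice = 2|A n B| / (|A| + |B|)};
#' both are defined as 1 when the two masks are empty, and
#' \code{dice_loss = 1 - dice}.
#'
#' @param mask_a,mask_b binary (logical or 0/1) matrices of identical shape.
#' @return List with \code{iou}, \code{dice}, and \code{dice_loss}.
#' @export
overlap_metrics <- function(mask_a, mask_b) {
  if (!all(dim(mask_a) == dim(mask_b)))
    stop("mask shapes differ: ", paste(dim(mask_a), collapse = "x"), " vs ",
         paste(dim(mask_b), collapse = "x"))
  a <- mask_a > 0; b <- mask_b > 0
  inter <- sum(a & b)
  union <- sum(a | b)
  sa <- sum(a); sb <- sum(b)
  iou <- if (union == 0L) 1 else inter / union
  dice <- if (sa + sb == 0L) 1 else 2 * inter / (sa + sb)
  list(iou = iou, dice = dice, dice_loss = 1 - dice)
}
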