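#' Tile specification for streamed image traversal
#'
#' @param tile_size tile edge length in pixels (>= 1).
#' @return A `tile_spec` (tiles are disjoint, row-major, truncated at the
#'   image edge).
#' @export
tile_spec <- function(tile_size = 1024L) {
  tile_size <- as.integer(tile_size)
  stopifnot(tile_size >= 1L)
  structure(list(tile_size = tile_size, overlap = 0L), class = "tile_spec")
}

#' Enumerate the pixel windows tiling an image
#'
#' Windows are disjoint, cover the image exactly once, and are traversed
#' row-major; edge tiles are truncated.
#'
#' @param image_shape integer `c(h, w)` (extra dimensions ignored).
#' @param spec a [tile_spec()].
#' @return Tibble with columns `r0`, `c0` (1-based top-left), `h`, `w`.
#' @export
iter_tiles <- function(image_shape, spec = tile_spec()) {
  h <- as.integer(image_shape[1L]); w <- as.integer(image_shape[2L])
  ts <- spec$tile_size
  r0 <- seq(1L, h, by = ts)
  c0 <- seq(1L, w, by = ts)
  g <- expand.grid(c0 = c0, r0 = r0)  # row-major: c varies fastest
  tibble::tibble(r0 = g$r0, c0 = g$c0,
                 h = pmin(ts, h - g$r0 + 1L),
                 w = pmin(ts, w - g$c0 + 1L))
}

#' Per-cell intensity quantification, streamed over tiles
#'
#' Computes summary statistics of one image channel over the pixels of
#' each cell — a pixel belongs to a cell when its centre falls inside the
#' cell's boundary polygon (even-odd rule, boundary inclusive), or when a
#' label mask image assigns it the cell's label. The image is visited tile
#' by tile and never materialized as a whole: per-cell running sums,
#' counts and maxima are merged across tiles, so peak memory scales with
#' the tile size plus the number of cells, not the image.
#'
#' @param image a `pixel_image` registered into the sample's micrometre
#'   frame (typically lazy/tiled on disk).
#' @param cell_layer a [cell_layer()] whose boundaries to quantify over.
#' @param channel channel index or name of `image`.
#' @param stats subset of `c("mean", "sum", "max")`. The median is not
#'   offered: it cannot be merged across tiles.
#' @param spec a [tile_spec()].
#' @param boundary_type `"cellular"` (default) or `"nuclear"`.
#' @param label_mask optional `pixel_image` of integer cell labels (values
#'   index into `cell_layer`'s rows, 0 = background); takes precedence
#'   over polygons.
#' @param column_prefix prefix for the new columns; defaults to the
#'   channel name.
#' @return The `cell_layer` with columns `<prefix>_<stat>` appended to its
#'   cell table; cells with no covered pixels get NA and a warning.
#' @export
quantify_intensity <- function(image, cell_layer, channel = 1L,
                               stats = c("mean", "sum", "max"),
                               spec = tile_spec(),
                               boundary_type = c("cellular", "nuclear"),
                               label_mask = NULL, column_prefix = NULL) {
  boundary_type <- match.arg(boundary_type)
  stats <- match.arg(stats, several.ok = TRUE)
  ch <- resolve_channel(image, channel)
  prefix <- column_prefix %||% image$channel_names[ch]
  n <- n_cells(cell_layer)
  ids <- cell_layer$cell_table$cell_id

  use_mask <- !is.null(label_mask)
  if (!use_mask) {
    b <- cell_layer$boundaries
    b <- b[b$boundary_type == boundary_type, , drop = FALSE]
    if (nrow(b) == 0L) {
      stop(sprintf("no %s boundaries (and no label mask) available",
                   boundary_type), call. = FALSE)
    }
    bidx <- match(b$cell_id, ids)
    bboxes <- t(vapply(b$coords, ring_bbox, numeric(4L)))
  } else {
    stopifnot(identical(label_mask$shape[1:2], image$shape[1:2]))
  }

  s <- image$pixel_size
  acc_sum <- numeric(n); acc_cnt <- numeric(n)
  acc_max <- rep(-Inf, n)

  wins <- iter_tiles(image$shape, spec)
  for (t in seq_len(nrow(wins))) {
    r0 <- wins$r0[t]; c0 <- wins$c0[t]; th <- wins$h[t]; tw <- wins$w[t]
    tile <- img_read_region(image, r0, c0, th, tw)
    if (length(dim(tile)) == 3L) tile <- tile[, , ch]
    if (use_mask) {
      mtile <- img_read_region(label_mask, r0, c0, th, tw)
      if (length(dim(mtile)) == 3L) mtile <- mtile[, , 1L]
      lab <- as.integer(round(as.vector(mtile)))
      hit <- which(lab >= 1L & lab <= n)
      if (length(hit)) {
        v <- as.vector(tile)[hit]
        li <- lab[hit]
        ts_ <- rowsum(v, li)
        tc <- rowsum(rep(1, length(hit)), li)
        tgt <- as.integer(rownames(ts_))
        acc_sum[tgt] <- acc_sum[tgt] + ts_[, 1L]
        acc_cnt[tgt] <- acc_cnt[tgt] + tc[, 1L]
        tm <- tapply(v, li, max)
        acc_max[tgt] <- pmax(acc_max[tgt], as.numeric(tm))
      }
    } else {
      # tile extent in micrometres, honouring the image origin
      o <- image$origin %||% c(0, 0)
      tx0 <- o[1L] + (c0 - 1L) * s; tx1 <- o[1L] + (c0 + tw - 1L) * s
      ty0 <- o[2L] + (r0 - 1L) * s; ty1 <- o[2L] + (r0 + th - 1L) * s
      cand <- which(bboxes[, "xmin"] < tx1 & bboxes[, "xmax"] > tx0 &
                      bboxes[, "ymin"] < ty1 & bboxes[, "ymax"] > ty0)
      if (length(cand) == 0L) next
      # pixel-centre coordinates of the tile, row-major
      cx <- o[1L] + ((c0:(c0 + tw - 1L)) - 0.5) * s
      cy <- o[2L] + ((r0:(r0 + th - 1L)) - 0.5) * s
      for (k in cand) {
        ring <- b$coords[[k]]
        bb <- bboxes[k, ]
        csel <- which(cx >= bb["xmin"] & cx <= bb["xmax"])
        rsel <- which(cy >= bb["ymin"] & cy <= bb["ymax"])
        if (!length(csel) || !length(rsel)) next
        pts <- cbind(rep(cx[csel], each = length(rsel)),
                     rep(cy[rsel], times = length(csel)))
        inside <- points_in_polygon(pts, ring)
        if (!any(inside)) next
        sub <- tile[rsel, csel, drop = FALSE]
        v <- as.vector(sub)[inside]
        i <- bidx[k]
        acc_sum[i] <- acc_sum[i] + sum(v)
        acc_cnt[i] <- acc_cnt[i] + length(v)
        acc_max[i] <- max(acc_max[i], max(v))
      }
    }
  }

  uncovered <- acc_cnt == 0
  if (any(uncovered)) {
    warning(sprintf("%d cell(s) cover no image pixels; statistics set to NA",
                    sum(uncovered)), call. = FALSE)
  }
  ct <- cell_layer$cell_table
  if ("sum" %in% stats) {
    ct[[paste0(prefix, "_sum")]] <- ifelse(uncovered, NA_real_, acc_sum)
  }
  if ("mean" %in% stats) {
    ct[[paste0(prefix, "_mean")]] <- ifelse(uncovered, NA_real_,
                                            acc_sum / acc_cnt)
  }
  if ("max" %in% stats) {
    ct[[paste0(prefix, "_max")]] <- ifelse(uncovered, NA_real_, acc_max)
  }
  cell_layer$cell_table <- ct
  cell_layer
}
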