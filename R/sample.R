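#' The per-section sample container
#'
#' A `spat_sample` holds all data of one tissue section in six categories:
#' `images` (named `pixel_image`s), `transcripts` (a tibble of molecule
#' locations, possibly lazy), `cells` (named `cell_layer`s), `units`
#' (named `unit_layer`s), `annotations` (named `polygon_set`s labelling
#' histology) and `regions` (named `polygon_set`s delineating structural
#' units such as TMA cores). All spatial coordinates live in one shared
#' micrometre frame anchored to the top-left corner of the primary
#' fluorescence image: x runs rightward along columns, y downward along
#' rows.
#'
#' @param uid unique sample identifier; minted when NULL.
#' @param metadata named list of sample-level key-value pairs.
#' @param images named list of [pixel_image()] objects.
#' @param transcripts tibble with columns `x`, `y` (micrometres), `gene`,
#'   and optionally `quality` and `cell_id`; or NULL.
#' @param cells named list of [cell_layer()] objects.
#' @param units named list of [unit_layer()] objects.
#' @param annotations named list of `polygon_set`s with scope "annotation".
#' @param regions named list of `polygon_set`s with scope "region".
#' @return A `spat_sample`.
#' @export
spat_sample <- function(uid = NULL, metadata = list(), images = list(),
                        transcripts = NULL, cells = list(), units = list(),
                        annotations = list(), regions = list()) {
  if (is.null(uid)) uid <- mint_uid()
  if (!is.null(transcripts) && !inherits(transcripts, "lazy_table")) {
    transcripts <- validate_transcripts(transcripts)
  }
  stopifnot(all(vapply(images, inherits, TRUE, "pixel_image")),
            all(vapply(cells, inherits, TRUE, "cell_layer")),
            all(vapply(units, inherits, TRUE, "unit_layer")),
            all(vapply(annotations, inherits, TRUE, "polygon_set")),
            all(vapply(regions, inherits, TRUE, "polygon_set")))
  structure(list(uid = uid, metadata = metadata, images = images,
                 transcripts = transcripts, cells = cells, units = units,
                 annotations = annotations, regions = regions),
            class = "spat_sample")
}

validate_transcripts <- function(tx) {
  tx <- tibble::as_tibble(tx)
  stopifnot(all(c("x", "y", "gene") %in% names(tx)))
  if (nrow(tx) > 0L) {
    if (!all(is.finite(tx$x)) || !all(is.finite(tx$y))) {
      stop("transcript coordinates must be finite", call. = FALSE)
    }
    if (any(!nzchar(tx$gene))) stop("gene labels must be non-empty", call. = FALSE)
  }
  tx
}

#' Mint a unique sample identifier
#'
#' Random 128-bit identifier rendered as 32 hex characters, drawn from R's
#' RNG so tests can seed it.
#' @export
mint_uid <- function() {
  paste(sprintf("%02x", sample.int(256L, 16L, replace = TRUE) - 1L),
        collapse = "")
}

#' @export
print.spat_sample <- function(x, ...) {
  n_tx <- if (is.null(x$transcripts)) 0L else table_nrow(x$transcripts)
  cat(sprintf(paste0("<spat_sample %s>\n  images: %s\n  transcripts: %d\n",
                     "  cells: %s\n  units: %s\n  annotations: %s\n",
                     "  regions: %s\n"),
              substr(x$uid, 1L, 8L), named_count(x$images), n_tx,
              named_count(x$cells), named_count(x$units),
              named_count(x$annotations), named_count(x$regions)))
  invisible(x)
}

named_count <- function(l) {
  if (length(l) == 0L) "none" else paste(names(l), collapse = ", ")
}

#' @rdname spat_sample
#' @param x a `spat_sample`.
#' @export
sample_uid <- function(x) x$uid

# Primary image: the first one, by convention the run's nuclear
# fluorescence image which anchors the coordinate frame.
primary_image <- function(x) if (length(x$images)) x$images[[1L]] else NULL

#' Materialized transcript table of a sample
#' @param x a `spat_sample`.
#' @return Tibble with columns x, y, gene, ... or an empty transcript
#'   tibble when the sample has none.
#' @export
sample_transcripts <- function(x) {
  if (is.null(x$transcripts)) {
    return(tibble::tibble(x = numeric(), y = numeric(), gene = character()))
  }
  table_materialize(x$transcripts)
}

#' Record counts per data category
#' @param x a `spat_sample`.
#' @return Tibble with columns `category` and `n`.
#' @export
sample_summary <- function(x) {
  tibble::tibble(
    category = c("images", "transcripts", "cells", "units",
                 "annotations", "regions"),
    n = c(length(x$images),
          if (is.null(x$transcripts)) 0L else table_nrow(x$transcripts),
          sum(vapply(x$cells, n_cells, 0L)),
          sum(vapply(x$units, function(u) nrow(u$matrix), 0L)),
          sum(vapply(x$annotations, nrow, 0L)),
          sum(vapply(x$regions, nrow, 0L)))
  )
}

#' Tight bounding box of a sample in micrometres
#'
#' The extent of the primary image when one exists, otherwise the bounding
#' box of all cell centroids.
#' @param x a `spat_sample`.
#' @return Named numeric vector (xmin, ymin, xmax, ymax).
#' @export
get_extent <- function(x) {
  img <- primary_image(x)
  if (!is.null(img)) return(img_extent(img))
  cents <- do.call(rbind, lapply(x$cells, function(l) {
    cbind(l$cell_table$centroid_x, l$cell_table$centroid_y)
  }))
  if (is.null(cents) || nrow(cents) == 0L) {
    stop("no extent: sample has no image and no cells", call. = FALSE)
  }
  c(xmin = min(cents[, 1L]), ymin = min(cents[, 2L]),
    xmax = max(cents[, 1L]), ymax = max(cents[, 2L]))
}

#' Crop a sample to a polygon
#'
#' Cells, spatial units (by centroid) and transcripts (by point) are kept
#' iff inside the polygon (even-odd rule, boundary inclusive); whole matrix
#' rows and boundary polygons follow their cells, and boundaries may
#' protrude beyond the polygon. Images are cropped to the polygon's
#' pixel-aligned bounding box intersected with the image; annotation and
#' region polygons are clipped to that bounding box. With
#' `shift_origin = TRUE` all coordinates are translated so the bounding-box
#' minimum maps to (0, 0); the applied offset is recorded in
#' `metadata$crop_offset` so the crop is invertible.
#'
#' @param x a `spat_sample`.
#' @param polygon an n-by-2 ring matrix in micrometres.
#' @param shift_origin translate coordinates to the cropped origin?
#'   Defaults to FALSE for ad-hoc crops; region-based assembly uses TRUE.
#' @return A cropped `spat_sample` (possibly empty; a polygon outside the
#'   extent yields an empty sample with a warning, not an error).
#' @export
crop_sample <- function(x, polygon, shift_origin = FALSE) {
  polygon <- as_ring(polygon)
  bb <- ring_bbox(polygon)
  img0 <- primary_image(x)

  # pixel-aligned bounding box on the primary grid (or raw bbox without one)
  if (!is.null(img0)) {
    s0 <- img0$pixel_size
    o0 <- img0$origin
    c0 <- floor((bb["xmin"] - o0[1L]) / s0); r0 <- floor((bb["ymin"] - o0[2L]) / s0)
    c1 <- ceiling((bb["xmax"] - o0[1L]) / s0); r1 <- ceiling((bb["ymax"] - o0[2L]) / s0)
    origin <- c(x = o0[1L] + unname(c0) * s0, y = o0[2L] + unname(r0) * s0)
    clip_box <- c(xmin = o0[1L] + unname(c0) * s0,
                  ymin = o0[2L] + unname(r0) * s0,
                  xmax = o0[1L] + unname(c1) * s0,
                  ymax = o0[2L] + unname(r1) * s0)
  } else {
    origin <- c(x = unname(bb["xmin"]), y = unname(bb["ymin"]))
    clip_box <- bb
  }

  off <- if (shift_origin) origin else c(x = 0, y = 0)

  images <- list()
  for (nm in names(x$images)) {
    img <- x$images[[nm]]
    s <- img$pixel_size
    o <- img$origin
    pc0 <- max(floor((bb["xmin"] - o[1L]) / s) + 1, 1L)
    pr0 <- max(floor((bb["ymin"] - o[2L]) / s) + 1, 1L)
    pc1 <- min(ceiling((bb["xmax"] - o[1L]) / s), img$shape[2L])
    pr1 <- min(ceiling((bb["ymax"] - o[2L]) / s), img$shape[1L])
    if (pc0 > pc1 || pr0 > pr1) {
      warning(sprintf("crop polygon does not intersect image '%s'; dropped", nm),
              call. = FALSE)
      next
    }
    cropped <- img_crop_pixels(img, as.integer(pr0), as.integer(pr1),
                               as.integer(pc0), as.integer(pc1))
    if (shift_origin) {
      cropped$origin <- cropped$origin - c(off["x"], off["y"])
    }
    images[[nm]] <- cropped
  }

  tx <- NULL
  if (!is.null(x$transcripts)) {
    tx <- sample_transcripts(x)
    if (nrow(tx) > 0L) {
      keep <- points_in_polygon(cbind(tx$x, tx$y), polygon)
      tx <- tx[keep, , drop = FALSE]
    }
    if (shift_origin && nrow(tx) > 0L) {
      tx$x <- tx$x - off["x"]; tx$y <- tx$y - off["y"]
    }
  }

  cells <- lapply(x$cells, function(l) {
    keep <- points_in_polygon(
      cbind(l$cell_table$centroid_x, l$cell_table$centroid_y), polygon)
    sub <- cell_layer_subset(l, l$cell_table$cell_id[keep])
    if (shift_origin) sub <- shift_cell_layer(sub, off)
    sub
  })
  units <- lapply(x$units, function(l) {
    keep <- points_in_polygon(
      cbind(l$unit_table$centroid_x, l$unit_table$centroid_y), polygon)
    sub <- unit_layer_subset(l, l$unit_table$unit_id[keep])
    if (shift_origin) sub <- shift_unit_layer(sub, off)
    sub
  })

  clip_set <- function(ps) {
    kept <- list(); nms <- character(); cls <- character()
    for (i in seq_len(nrow(ps))) {
      cl <- clip_ring_rect(ps$coords[[i]], clip_box["xmin"], clip_box["ymin"],
                           clip_box["xmax"], clip_box["ymax"])
      if (!is.null(cl)) {
        if (shift_origin) cl <- sweep(cl, 2L, off)
        kept <- c(kept, list(cl)); nms <- c(nms, ps$name[i])
        cls <- c(cls, ps$class_label[i])
      }
    }
    polygon_set(nms, cls, kept, scope = polygon_scope(ps))
  }
  annotations <- lapply(x$annotations, clip_set)
  regions <- lapply(x$regions, clip_set)

  md <- x$metadata
  if (shift_origin) {
    prev <- md$crop_offset %||% c(x = 0, y = 0)
    md$crop_offset <- c(x = unname(prev["x"] + off["x"]),
                        y = unname(prev["y"] + off["y"]))
  }

  total_kept <- sum(vapply(cells, n_cells, 0L)) +
    (if (is.null(tx)) 0L else nrow(tx))
  if (total_kept == 0L && length(x$cells) + length(x$images) > 0L) {
    # not an error by contract; flag for callers such as from_regions
    warning("crop polygon retained no cells or transcripts", call. = FALSE)
  }

  spat_sample(uid = x$uid, metadata = md, images = images, transcripts = tx,
              cells = cells, units = units, annotations = annotations,
              regions = regions)
}

shift_cell_layer <- function(l, off) {
  l$cell_table$centroid_x <- l$cell_table$centroid_x - off["x"]
  l$cell_table$centroid_y <- l$cell_table$centroid_y - off["y"]
  l$boundaries$coords <- lapply(l$boundaries$coords, function(p) sweep(p, 2L, off))
  l
}

shift_unit_layer <- function(l, off) {
  l$unit_table$centroid_x <- l$unit_table$centroid_x - off["x"]
  l$unit_table$centroid_y <- l$unit_table$centroid_y - off["y"]
  l$shapes$coords <- lapply(l$shapes$coords, function(p) sweep(p, 2L, off))
  l
}

# ---- lazy tables (transcripts) ------------------------------------------

new_lazy_table <- function(reader, n, checksum = NULL) {
  env <- new.env(parent = emptyenv())
  env$cache <- NULL
  env$n_reads <- 0L
  env$reader <- reader
  env$checksum <- checksum
  env$verified <- is.null(checksum)
  structure(list(env = env, n = as.integer(n)), class = "lazy_table")
}

#' @export
print.lazy_table <- function(x, ...) {
  st <- if (is.null(x$env$cache)) "lazy" else "in memory"
  cat(sprintf("<lazy_table: %d row(s), %s>\n", x$n, st))
  invisible(x)
}

table_nrow <- function(x) {
  if (inherits(x, "lazy_table")) x$n else nrow(x)
}

table_materialize <- function(x) {
  if (!inherits(x, "lazy_table")) return(tibble::as_tibble(x))
  env <- x$env
  if (!is.null(env$cache)) return(env$cache)
  if (!env$verified) {
    got <- digest::digest(env$checksum$path, algo = "sha256", file = TRUE)
    if (!identical(got, env$checksum$sha256)) {
      stop(sprintf("corruption error: static file '%s' digest mismatch",
                   env$checksum$path), call. = FALSE)
    }
    env$verified <- TRUE
  }
  env$n_reads <- env$n_reads + 1L
  env$cache <- validate_transcripts(env$reader())
  env$cache
}

table_read_count <- function(x) {
  if (inherits(x, "lazy_table")) x$env$n_reads else NA_integer_
}
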