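#' Import polygons from GeoJSON (QuPath classification dialect)
#'
#' Reads a FeatureCollection of Polygon/MultiPolygon features into a
#' [polygon_set()]. The class label is taken from the QuPath-style
#' `classification` property (`{"name": ...}` or a bare string) and falls
#' back to `"unclassified"`. A top-level `coordinate_unit` property of
#' `"micron"` (the default when absent) or `"pixel"` declares the units;
#' pixel coordinates — the QuPath convention — are converted to micrometres
#' using the file's `pixel_size` property or the `pixel_size` argument
#' (typically the primary image's).
#'
#' @param path GeoJSON file.
#' @param scope `"annotation"` or `"region"`.
#' @param pixel_size micrometres per pixel, used only for pixel-unit files
#'   lacking their own `pixel_size` property.
#' @return A `polygon_set`. Non-polygon geometries are skipped with a
#'   warning.
#' @export
import_annotations_geojson <- function(path, scope = c("annotation", "region"),
                                       pixel_size = NULL) {
  scope <- match.arg(scope)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  }
  unit <- gj$coordinate_unit %||% "micron"
  scale <- 1
  if (identical(unit, "pixel")) {
    ps <- gj$pixel_size %||% pixel_size
    if (is.null(ps)) {
      stop("pixel-unit GeoJSON requires a pixel_size", call. = FALSE)
    }
    scale <- as.numeric(ps)
  }
  names_ <- character(); classes <- character(); rings <- list()
  feats <- gj$features %||% list()
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    geom <- f$geometry
    props <- f$properties %||% list()
    cls <- props$classification
    cls <- if (is.list(cls)) cls$name %||% "unclassified"
           else if (is.character(cls)) cls else "unclassified"
    stem <- props$name %||% sprintf("%s_%d", scope, i)
    if (identical(geom$type, "Polygon")) {
      rings <- c(rings, list(coords_to_ring(geom$coordinates[[1L]]) * scale))
      names_ <- c(names_, stem); classes <- c(classes, cls)
    } else if (identical(geom$type, "MultiPolygon")) {
      for (k in seq_along(geom$coordinates)) {
        rings <- c(rings, list(coords_to_ring(geom$coordinates[[k]][[1L]]) * scale))
        names_ <- c(names_, sprintf("%s_%d", stem, k))
        classes <- c(classes, cls)
      }
    } else {
      warning(sprintf("skipping non-polygon geometry '%s' in feature %d",
                      geom$type %||% "NULL", i), call. = FALSE)
    }
  }
  # de-duplicate names defensively (files may repeat them)
  if (anyDuplicated(names_)) names_ <- make.unique(names_, sep = "_")
  polygon_set(names_, classes, rings, scope = scope)
}

coords_to_ring <- function(cc) {
  m <- do.call(rbind, lapply(cc, function(p) c(p[[1L]], p[[2L]])))
  as_ring(m)
}

#' Export a polygon set to GeoJSON
#'
#' Writes a FeatureCollection with explicitly closed rings, QuPath-style
#' `classification` properties and a top-level
#' `coordinate_unit = "micron"` declaration, so the file round-trips
#' through [import_annotations_geojson()] and opens in QuPath-compatible
#' tools.
#'
#' @param polygon_set a [polygon_set()].
#' @param path output file.
#' @return The path, invisibly.
#' @export
export_annotations_geojson <- function(polygon_set, path) {
  feats <- lapply(seq_len(nrow(polygon_set)), function(i) {
    ring <- polygon_set$coords[[i]]
    closed <- rbind(ring, ring[1L, , drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(closed)),
                                                   function(r) closed[r, ]))),
         properties = list(name = polygon_set$name[i],
                           objectType = polygon_scope(polygon_set),
                           classification = list(name = polygon_set$class_label[i])))
  })
  gj <- list(type = "FeatureCollection", coordinate_unit = "micron",
             features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

# Boundaries <-> GeoJSON: one feature per ring with cell_id/boundary_type
# properties, micrometre units.
write_boundaries_geojson <- function(boundaries, path) {
  feats <- lapply(seq_len(nrow(boundaries)), function(i) {
    ring <- boundaries$coords[[i]]
    closed <- rbind(ring, ring[1L, , drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(closed)),
                                                   function(r) closed[r, ]))),
         properties = list(cell_id = boundaries$cell_id[i],
                           boundary_type = boundaries$boundary_type[i]))
  })
  gj <- list(type = "FeatureCollection", coordinate_unit = "micron",
             features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_boundaries_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- gj$features %||% list()
  tibble::tibble(
    cell_id = vapply(feats, function(f) f$properties$cell_id, ""),
    boundary_type = vapply(feats, function(f) f$properties$boundary_type, ""),
    coords = lapply(feats, function(f) coords_to_ring(f$geometry$coordinates[[1L]]))
  )
}

# Unit shapes reuse the boundary reader/writer with unit_id keys.
write_shapes_geojson <- function(shapes, path) {
  b <- tibble::tibble(cell_id = shapes$unit_id, boundary_type = "shape",
                      coords = shapes$coords)
  write_boundaries_geojson(b, path)
}

read_shapes_geojson <- function(path) {
  b <- read_boundaries_geojson(path)
  tibble::tibble(unit_id = b$cell_id, coords = b$coords)
}
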