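#' Cell layers: one segmentation's worth of per-cell data
#'
#' A cell layer couples a non-negative count matrix (cells x features) with
#' a per-cell tibble (unique `cell_id`, centroids in micrometres, optional
#' `cell_type` and quantified intensity columns), a per-feature tibble, and
#' optional nuclear/cellular boundary polygons keyed by `cell_id`. Multiple
#' layers on one sample hold the results of different segmentation
#' algorithms side by side.
#'
#' @param matrix cells x features count matrix (base or `Matrix`),
#'   non-negative; rownames/colnames optional.
#' @param cell_table tibble with columns `cell_id` (unique), `centroid_x`,
#'   `centroid_y`; one row per matrix row, same order.
#' @param feature_table tibble with column `feature`; one row per matrix
#'   column. Defaults to the matrix column names.
#' @param boundaries tibble with columns `cell_id`, `boundary_type`
#'   (`"nuclear"` or `"cellular"`) and `coords` (list of rings), or NULL.
#' @return A `cell_layer` object.
#' @export
cell_layer <- function(matrix, cell_table, feature_table = NULL,
                       boundaries = NULL) {
  matrix <- as_count_matrix(matrix)
  cell_table <- tibble::as_tibble(cell_table)
  stopifnot(all(c("cell_id", "centroid_x", "centroid_y") %in% names(cell_table)))
  cell_table$cell_id <- as.character(cell_table$cell_id)
  if (anyDuplicated(cell_table$cell_id)) {
    stop("cell_ids must be unique within a layer", call. = FALSE)
  }
  if (nrow(matrix) != nrow(cell_table)) {
    stop("matrix row count must equal cell_table row count", call. = FALSE)
  }
  if (is.null(feature_table)) {
    feat <- colnames(matrix) %||% paste0("feature", seq_len(ncol(matrix)))
    feature_table <- tibble::tibble(feature = feat)
  }
  feature_table <- tibble::as_tibble(feature_table)
  stopifnot("feature" %in% names(feature_table))
  if (ncol(matrix) != nrow(feature_table)) {
    stop("matrix column count must equal feature_table row count", call. = FALSE)
  }
  rownames(matrix) <- cell_table$cell_id
  colnames(matrix) <- feature_table$feature
  if (!is.null(boundaries) && nrow(boundaries) > 0L) {
    boundaries <- tibble::as_tibble(boundaries)
    stopifnot(all(c("cell_id", "boundary_type", "coords") %in% names(boundaries)))
    boundaries$cell_id <- as.character(boundaries$cell_id)
    stopifnot(all(boundaries$boundary_type %in% c("nuclear", "cellular")))
    extra <- setdiff(boundaries$cell_id, cell_table$cell_id)
    if (length(extra)) {
      stop("boundary polygons must be keyed by known cell_ids", call. = FALSE)
    }
    boundaries$coords <- lapply(boundaries$coords, as_ring)
  } else {
    boundaries <- empty_boundaries()
  }
  structure(list(matrix = matrix, cell_table = cell_table,
                 feature_table = feature_table, boundaries = boundaries),
            class = "cell_layer")
}

empty_boundaries <- function() {
  tibble::tibble(cell_id = character(), boundary_type = character(),
                 coords = list())
}

as_count_matrix <- function(m) {
  if (!inherits(m, "Matrix")) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m <- Matrix::Matrix(m, sparse = TRUE)
  }
  m <- methods::as(m, "CsparseMatrix")
  if (any(m@x < 0)) stop("count matrix must be non-negative", call. = FALSE)
  m
}

#' @export
print.cell_layer <- function(x, ...) {
  cat(sprintf("<cell_layer: %d cells x %d features, %d boundary polygon(s)>\n",
              nrow(x$matrix), ncol(x$matrix), nrow(x$boundaries)))
  invisible(x)
}

#' @rdname cell_layer
#' @param x a `cell_layer`.
#' @export
n_cells <- function(x) UseMethod("n_cells")

#' @export
n_cells.cell_layer <- function(x) nrow(x$matrix)

# Subset a cell layer to a set of cell_ids (order of `keep`), carrying
# matrix rows and boundaries along.
cell_layer_subset <- function(layer, keep_ids) {
  idx <- match(keep_ids, layer$cell_table$cell_id)
  stopifnot(!anyNA(idx))
  b <- layer$boundaries[layer$boundaries$cell_id %in% keep_ids, , drop = FALSE]
  cell_layer(layer$matrix[idx, , drop = FALSE],
             layer$cell_table[idx, , drop = FALSE],
             layer$feature_table, b)
}

#' Spatial-unit layers: omics data over arbitrarily shaped areas
#'
#' Like a cell layer but for non-cell spatial units (capture spots, tissue
#' compartments): matrix + per-unit table + per-feature table, and one shape
#' polygon per unit (required).
#'
#' @param matrix units x features matrix, non-negative.
#' @param unit_table tibble with `unit_id` (unique), `centroid_x`,
#'   `centroid_y`.
#' @param feature_table tibble with column `feature`.
#' @param shapes tibble with columns `unit_id`, `coords` (list of rings);
#'   every unit must have exactly one shape.
#' @return A `unit_layer` object.
#' @export
unit_layer <- function(matrix, unit_table, feature_table = NULL, shapes) {
  matrix <- as_count_matrix(matrix)
  unit_table <- tibble::as_tibble(unit_table)
  stopifnot(all(c("unit_id", "centroid_x", "centroid_y") %in% names(unit_table)))
  unit_table$unit_id <- as.character(unit_table$unit_id)
  if (anyDuplicated(unit_table$unit_id)) {
    stop("unit_ids must be unique", call. = FALSE)
  }
  if (nrow(matrix) != nrow(unit_table)) {
    stop("matrix row count must equal unit_table row count", call. = FALSE)
  }
  if (is.null(feature_table)) {
    feat <- colnames(matrix) %||% paste0("feature", seq_len(ncol(matrix)))
    feature_table <- tibble::tibble(feature = feat)
  }
  feature_table <- tibble::as_tibble(feature_table)
  if (ncol(matrix) != nrow(feature_table)) {
    stop("matrix column count must equal feature_table row count", call. = FALSE)
  }
  shapes <- tibble::as_tibble(shapes)
  stopifnot(all(c("unit_id", "coords") %in% names(shapes)))
  shapes$unit_id <- as.character(shapes$unit_id)
  if (!setequal(shapes$unit_id, unit_table$unit_id) ||
      nrow(shapes) != nrow(unit_table)) {
    stop("every unit must have exactly one shape polygon", call. = FALSE)
  }
  shapes$coords <- lapply(shapes$coords, as_ring)
  rownames(matrix) <- unit_table$unit_id
  colnames(matrix) <- feature_table$feature
  structure(list(matrix = matrix, unit_table = unit_table,
                 feature_table = feature_table, shapes = shapes),
            class = "unit_layer")
}

#' @export
print.unit_layer <- function(x, ...) {
  cat(sprintf("<unit_layer: %d units x %d features>\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

unit_layer_subset <- function(layer, keep_ids) {
  idx <- match(keep_ids, layer$unit_table$unit_id)
  stopifnot(!anyNA(idx))
  sh <- layer$shapes[match(keep_ids, layer$shapes$unit_id), , drop = FALSE]
  unit_layer(layer$matrix[idx, , drop = FALSE],
             layer$unit_table[idx, , drop = FALSE],
             layer$feature_table, sh)
}
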