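#' Cellular composition per group
#'
#' Proportion of each cell type among the cells of each group, where a
#' group is a metadata value (e.g. condition) or the sample UID itself.
#' Rows sum to 1; cell types absent from a group get 0.
#'
#' @param experiment a `spat_experiment`.
#' @param group_key metadata column defining groups, or `"uid"`.
#' @param celltype_key column of the cell tables holding the cell type.
#' @param cell_layer layer name; defaults to each sample's first layer.
#' @return A wide tibble (class `composition_tbl`): `group` plus one
#'   proportion column per cell type.
#' @export
cell_composition <- function(experiment, group_key = "uid",
                             celltype_key = "cell_type", cell_layer = NULL) {
  if (!group_key %in% names(experiment$metadata)) {
    stop(sprintf("unknown metadata column '%s'", group_key), call. = FALSE)
  }
  rows <- purrr::map_dfr(iterate(experiment), function(pair) {
    l <- pick_cell_layer(pair$sample, cell_layer)
    if (!celltype_key %in% names(l$cell_table)) {
      stop(sprintf("column '%s' missing from cell table of sample %s",
                   celltype_key, sample_uid(pair$sample)), call. = FALSE)
    }
    tibble::tibble(group = as.character(pair$metadata[[group_key]][1L]),
                   cell_type = as.character(l$cell_table[[celltype_key]]))
  })
  out <- rows |>
    dplyr::count(.data$group, .data$cell_type) |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(prop = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select(-"n") |>
    tidyr::pivot_wider(names_from = "cell_type", values_from = "prop",
                       values_fill = 0, names_sort = TRUE)
  structure(out, class = c("composition_tbl", class(out)))
}

pick_cell_layer <- function(sample, cell_layer = NULL) {
  if (length(sample$cells) == 0L) {
    stop(sprintf("sample %s has no cell layers", sample_uid(sample)),
         call. = FALSE)
  }
  if (is.null(cell_layer)) return(sample$cells[[1L]])
  if (!cell_layer %in% names(sample$cells)) {
    stop(sprintf("unknown cell layer '%s'", cell_layer), call. = FALSE)
  }
  sample$cells[[cell_layer]]
}

#' Cell-type density inside polygons
#'
#' Counts cell centroids of each type inside each polygon of a named
#' annotation or region set and divides by the polygon area, reported as
#' cells per square millimetre.
#'
#' @param sample a `spat_sample`.
#' @param polygon_set_name name of a polygon set (annotations are searched
#'   first, then regions).
#' @param celltype_key cell-table column holding the cell type.
#' @param cell_layer layer name; defaults to the first.
#' @return Tibble with columns `polygon`, `class_label`, `cell_type`, `n`,
#'   `area_um2`, `density_per_mm2` (every polygon x observed type,
#'   zero-filled).
#' @export
cell_type_density <- function(sample, polygon_set_name,
                              celltype_key = "cell_type",
                              cell_layer = NULL) {
  ps <- sample$annotations[[polygon_set_name]] %||%
    sample$regions[[polygon_set_name]]
  if (is.null(ps)) {
    stop(sprintf("unknown polygon set '%s'", polygon_set_name),
         call. = FALSE)
  }
  l <- pick_cell_layer(sample, cell_layer)
  if (!celltype_key %in% names(l$cell_table)) {
    stop(sprintf("column '%s' missing from cell table", celltype_key),
         call. = FALSE)
  }
  cents <- cbind(l$cell_table$centroid_x, l$cell_table$centroid_y)
  types <- as.character(l$cell_table[[celltype_key]])
  all_types <- sort(unique(types))
  out <- purrr::map_dfr(seq_len(nrow(ps)), function(i) {
    area <- polygon_area(ps$coords[[i]])
    if (area <= 0) {
      stop(sprintf("invalid polygon '%s': zero area", ps$name[i]),
           call. = FALSE)
    }
    inside <- points_in_polygon(cents, ps$coords[[i]])
    cnt <- table(factor(types[inside], levels = all_types))
    tibble::tibble(polygon = ps$name[i], class_label = ps$class_label[i],
                   cell_type = all_types, n = as.integer(cnt),
                   area_um2 = area,
                   density_per_mm2 = as.numeric(cnt) / (area / 1e6))
  })
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' ties are preserved. A thin, range-checked wrapper around the standard
#' step-up implementation.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Differential expression between two cell groups
#'
#' Counts of both groups are normalized per cell to the median total of
#' the pooled groups, each shared feature is tested with a two-sided
#' Wilcoxon rank-sum test (normal approximation with tie correction), the
#' log2 fold change is computed on normalized group means with a 1e-9
#' pseudocount, and q-values are Benjamini-Hochberg over all tested
#' features. These are documented, deliberately simple defaults — the
#' analyses exist to be swappable.
#'
#' @param cells_a,cells_b `cell_layer`s or cells-by-features count
#'   matrices; each group needs >= 2 cells and the feature sets must
#'   overlap (the intersection is used, with a warning when partial).
#' @param epsilon pseudocount for the fold change.
#' @return Tibble (class `spat_dge`) with columns `feature`, `mean_a`,
#'   `mean_b`, `lfc`, `statistic` (z), `p_value`, `q_value`.
#' @export
differential_expression <- function(cells_a, cells_b, epsilon = 1e-9) {
  ma <- extract_counts(cells_a)
  mb <- extract_counts(cells_b)
  if (nrow(ma) < 2L || nrow(mb) < 2L) {
    stop("each group needs at least 2 cells", call. = FALSE)
  }
  shared <- intersect(colnames(ma), colnames(mb))
  if (length(shared) == 0L) {
    stop("feature mismatch: the groups share no features", call. = FALSE)
  }
  if (length(shared) < ncol(ma) || length(shared) < ncol(mb)) {
    warning(sprintf("using %d shared features (of %d / %d)", length(shared),
                    ncol(ma), ncol(mb)), call. = FALSE)
  }
  ma <- ma[, shared, drop = FALSE]
  mb <- mb[, shared, drop = FALSE]
  # median-total normalization over the pooled groups
  tot <- c(Matrix::rowSums(ma), Matrix::rowSums(mb))
  target <- stats::median(tot)
  sf <- ifelse(tot > 0, target / tot, 0)
  na <- nrow(ma); nb <- nrow(mb)
  ma <- as.matrix(ma) * sf[seq_len(na)]
  mb <- as.matrix(mb) * sf[na + seq_len(nb)]

  mean_a <- colMeans(ma); mean_b <- colMeans(mb)
  lfc <- log2((mean_a + epsilon) / (mean_b + epsilon))
  zp <- vapply(seq_along(shared), function(j) {
    rank_sum_z(ma[, j], mb[, j])
  }, numeric(2L))
  p <- zp[2L, ]
  tb <- tibble::tibble(feature = shared, mean_a = mean_a, mean_b = mean_b,
                       lfc = lfc, statistic = zp[1L, ], p_value = p,
                       q_value = bh_adjust(p))
  structure(tb, class = c("spat_dge", class(tb)))
}

extract_counts <- function(x) {
  if (inherits(x, "cell_layer")) return(x$matrix)
  if (inherits(x, "Matrix") || is.matrix(x)) {
    m <- x
    if (is.null(colnames(m))) colnames(m) <- paste0("feature", seq_len(ncol(m)))
    return(m)
  }
  stop("expected a cell_layer or a cells x features matrix", call. = FALSE)
}

# Two-sided Wilcoxon rank-sum z with tie correction; returns c(z, p).
rank_sum_z <- function(a, b) {
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sig2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sig2 <= 0) return(c(0, 1))
  z <- (u - mu) / sqrt(sig2)
  c(z, 2 * stats::pnorm(-abs(z)))
}

#' Pseudobulk aggregation of raw counts
#'
#' Sums the raw counts of all member cells per group, emulating bulk
#' profiles from single-cell data. Features are intersected across
#' samples (a warning reports drops) rather than zero-filled.
#'
#' @param experiment a `spat_experiment`.
#' @param group_key metadata column defining groups, or `"uid"`.
#' @param cell_layer layer name; defaults to each sample's first layer.
#' @return Long tibble (class `pseudobulk_tbl`) with columns `group`,
#'   `feature`, `count`.
#' @export
pseudobulk <- function(experiment, group_key = "uid", cell_layer = NULL) {
  if (!group_key %in% names(experiment$metadata)) {
    stop(sprintf("unknown metadata column '%s'", group_key), call. = FALSE)
  }
  pairs <- iterate(experiment)
  layers <- lapply(pairs, function(p) pick_cell_layer(p$sample, cell_layer))
  featsets <- lapply(layers, function(l) colnames(l$matrix))
  shared <- Reduce(intersect, featsets)
  if (length(shared) == 0L) {
    stop("empty feature intersection across samples", call. = FALSE)
  }
  if (any(vapply(featsets, length, 0L) != length(shared))) {
    warning(sprintf("features intersected across samples: %d kept",
                    length(shared)), call. = FALSE)
  }
  sums <- purrr::map_dfr(seq_along(pairs), function(i) {
    g <- as.character(pairs[[i]]$metadata[[group_key]][1L])
    cs <- Matrix::colSums(layers[[i]]$matrix[, shared, drop = FALSE])
    tibble::tibble(group = g, feature = shared, count = as.numeric(cs))
  })
  out <- sums |>
    dplyr::group_by(.data$group, .data$feature) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  structure(out, class = c("pseudobulk_tbl", class(out)))
}

#' @method tidy spat_dge
#' @export
tidy.spat_dge <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @method glance spat_dge
#' @export
glance.spat_dge <- function(x, ...) {
  tibble::tibble(n_features = nrow(x),
                 n_significant = sum(x$q_value < 0.05),
                 min_q = if (nrow(x)) min(x$q_value) else NA_real_)
}
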