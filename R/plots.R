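#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Stacked-bar plot of cellular composition
#' @param object a `composition_tbl` from [cell_composition()].
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot composition_tbl
#' @export
autoplot.composition_tbl <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"group",
                              names_to = "cell_type", values_to = "prop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$prop,
                                     fill = .data$cell_type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "proportion of cells", fill = "cell type") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression result
#' @param object a `spat_dge` from [differential_expression()].
#' @param q_cut significance threshold on the q-value.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot spat_dge
#' @export
autoplot.spat_dge <- function(object, q_cut = 0.05, ...) {
  d <- tibble::as_tibble(object)
  d$significant <- d$q_value < q_cut
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lfc,
                                  y = -log10(pmax(.data$p_value, 1e-300)),
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (A vs B)", y = "-log10 p",
                  colour = sprintf("q < %g", q_cut)) +
    ggplot2::theme_minimal()
}

#' Map of cell centroids coloured by a cell-table column
#' @param sample a `spat_sample`.
#' @param colour_by cell-table column to colour by.
#' @param cell_layer layer name; defaults to the first.
#' @return A ggplot (y axis reversed to match image orientation).
#' @export
plot_cell_map <- function(sample, colour_by = "cell_type",
                          cell_layer = NULL) {
  l <- pick_cell_layer(sample, cell_layer)
  d <- l$cell_table
  ggplot2::ggplot(d, ggplot2::aes(x = .data$centroid_x, y = .data$centroid_y,
                                  colour = .data[[colour_by]])) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}
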