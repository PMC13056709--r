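# ggplot2 views of the result types: preservation heatmap, composition
# bars, NES profile.

#' @rdname preservation
#' @param object A `preservation_matrix`.
#' @method autoplot preservation_matrix
#' @export
autoplot.preservation_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$day0_type, colnames(object$r)),
    y = factor(.data$day14_type, rev(rownames(object$r))),
    fill = .data$r)) +
    ggplot2::geom_tile(colour = "grey85") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  limits = c(-1, 1), name = "Pearson r") +
    ggplot2::labs(x = "Day 0 cell type", y = "Day 14 cell type",
                  title = sprintf("Identity preservation (%d genes)",
                                  object$n_genes_used)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Stacked composition bar chart
#'
#' @param comp A [composition()] tibble.
#' @param group_by Faceting column (default `"sample_id"` when present).
#' @return A ggplot object.
#' @export
plot_composition <- function(comp, group_by = NULL) {
  group_by <- group_by %||% intersect("sample_id", names(comp))[1]
  gg <- ggplot2::ggplot(comp, ggplot2::aes(
    x = .data$timepoint, y = .data$fraction, fill = .data$cell_type)) +
    ggplot2::geom_col(position = "stack", width = 0.7) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "Cells", fill = "Cell type") +
    ggplot2::theme_minimal()
  if (!is.null(group_by) && !is.na(group_by)) {
    gg <- gg + ggplot2::facet_wrap(group_by)
  }
  gg
}

#' @rdname gsea
#' @param object A `gsea_result`.
#' @param passing_only Show only sets that pass the NES and FDR thresholds.
#' @method autoplot gsea_result
#' @export
autoplot.gsea_result <- function(object, passing_only = FALSE, ...) {
  df <- if (passing_only) dplyr::filter(object, .data$passes) else object
  df <- dplyr::filter(df, !is.na(.data$nes))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$nes,
    y = stats::reorder(.data$set_name, .data$nes),
    fill = .data$passes)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = c(-attr(object, "nes_min"), 0,
                                       attr(object, "nes_min")),
                        linetype = c("dashed", "solid", "dashed"),
                        colour = "grey40") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#B2182B",
                                          `FALSE` = "grey70"),
                               name = "Passes") +
    ggplot2::labs(x = "Normalized enrichment score", y = NULL) +
    ggplot2::theme_minimal()
}
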