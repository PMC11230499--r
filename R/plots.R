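#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a PPBC-like classification
#'
#' Scatter of the regulon score against the proliferation score, one point
#' per cell, with the two half-max thresholds as dashed lines; PPBC-like
#' cells (upper-right quadrant) are highlighted.
#'
#' @param object A [classify_ppbc_like()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ppbc_classification <- function(object, ...) {
  thr <- attr(object, "thresholds")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$score_proliferation,
                               y = .data$score_regulon,
                               colour = .data$is_ppbc_like)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = thr[["proliferation"]], linetype = "dashed") +
    ggplot2::geom_hline(yintercept = thr[["regulon"]], linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "proliferation score (log2 feature sum)",
                  y = "regulon score (log2 feature sum)",
                  colour = "PPBC-like") +
    ggplot2::theme_minimal()
}

#' Plot per-sample cell-type proportions
#'
#' Stacked bars of the AV/HS/ME/unassigned fractions per sample, faceted by
#' lactation state, mirroring the usual epithelial-composition figure.
#'
#' @param proportions A [type_proportions()] result.
#' @return A ggplot object.
#' @export
plot_type_proportions <- function(proportions) {
  ggplot2::ggplot(proportions,
                  ggplot2::aes(x = .data$sample_id, y = .data$fraction,
                               fill = .data$celltype)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(~ .data$state, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "fraction of cells", fill = "cell type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot Venn region sizes
#'
#' Bar chart of the disjoint region sizes of a Venn partition.
#'
#' @param object A [venn_partition()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.venn_partition <- function(object, ...) {
  ggplot2::ggplot(tidy.venn_partition(object),
                  ggplot2::aes(x = stats::reorder(.data$region, -.data$n),
                               y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Venn region", y = "genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
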