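#' Plot per-category enrichment curves
#'
#' @param curves Tidy data.frame (category, bin, value) from
#'   [category_profile()].
#' @return A ggplot object.
#' @export
plot_category_profile <- function(curves) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$bin, y = .data$value,
                               colour = factor(.data$category))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "bin (5' to 3')", y = "normalized signal",
                  colour = "category") +
    ggplot2::theme_minimal()
}

#' Heatmap of a sorted, clustered promoter matrix
#'
#' @param rendered Output of [sort_and_render()].
#' @param filename Optional path; when given the heatmap is written there.
#' @export
plot_cluster_heatmap <- function(rendered, filename = NA) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("pheatmap is required for plotting")
  pheatmap::pheatmap(rendered$matrix, cluster_rows = FALSE,
                     cluster_cols = FALSE, show_rownames = FALSE,
                     gaps_row = utils::head(rendered$boundaries, -1),
                     filename = filename)
}
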