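#' Bar chart of peptide membership regions
#'
#' @param venn A Venn-count tibble from [venn_counts()].
#' @return A ggplot object.
#' @export
plot_venn_counts <- function(venn) {
  venn$region <- factor(venn$region, levels = venn$region)
  ggplot2::ggplot(venn, ggplot2::aes(x = .data$region, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = "database membership region", y = "peptides",
                  title = "Observed peptides by database membership") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Bar chart of contig classification per annotation version
#'
#' @param category_counts The `category_counts` tibble of a `pg_run`.
#' @return A ggplot object.
#' @export
plot_categories <- function(category_counts) {
  ggplot2::ggplot(category_counts,
                  ggplot2::aes(x = .data$category, y = .data$count,
                               fill = .data$version)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "contigs",
                  title = "Novel-peptide-supported contig classification") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}

#' Plot a pipeline run
#'
#' Combines the membership-region and classification bar charts (with
#' patchwork when available, otherwise returns the classification
#' panel).
#'
#' @param object A `pg_run`.
#' @param ... Unused.
#' @return A ggplot or patchwork object.
#' @method autoplot pg_run
#' @export
autoplot.pg_run <- function(object, ...) {
  p1 <- plot_venn_counts(object$venn)
  p2 <- plot_categories(object$category_counts)
  if (requireNamespace("patchwork", quietly = TRUE)) {
    p1 / p2
  } else {
    p2
  }
}
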