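# ggplot2 views of the result objects.

#' Volcano plot of homoeolog differential expression
#'
#' log2 fold change (TBF3 over BTF3) against -log10 p-value, coloured by
#' call direction, facetted by homoeolog and tissue.
#'
#' @param object a `homoeolog_de` object.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot homoeolog_de
#' @export
autoplot.homoeolog_de <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2fc,
                                  y = -log10(.data$p_value),
                                  colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(
      "up-in-TBF3" = "#d7301f", "up-in-BTF3" = "#0570b0", ns = "grey60")) +
    ggplot2::facet_grid(.data$homoeolog ~ .data$tissue) +
    ggplot2::labs(x = "log2 FC (TBF3 / BTF3)", y = "-log10 p",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of AS-event composition
#'
#' @param x an `as_summary` table from [as_summary_table()].
#' @return a ggplot of per-column event counts by type.
#' @export
plot_as_summary <- function(x) {
  d <- x |> filter(.data$type != "Total")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$column, y = .data$n_events,
                                  fill = .data$type)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "AS events", fill = "type") +
    ggplot2::theme_minimal()
}
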