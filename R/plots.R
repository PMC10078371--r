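# Plotting ---------------------------------------------------------------------

#' Seasonal trajectory of a weekly metric
#'
#' Line chart of one structural metric over season weeks, one line per
#' year — the standard view for judging whether within-season structure
#' repeats across years.
#'
#' @param metrics A weekly metric table from [series_metrics()].
#' @param metric Metric column to plot.
#' @return A ggplot object.
#' @export
plot_weekly_metrics <- function(metrics, metric = "connectance_bin") {
  ggplot2::ggplot(
    metrics,
    ggplot2::aes(x = .data$week, y = .data[[metric]],
                 colour = factor(.data$year), group = .data$year)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "season week", y = metric, colour = "year") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.bipartite_network <- function(object, ...) {
  el <- as_edge_list(object)
  ggplot2::ggplot(el, ggplot2::aes(x = .data$insect, y = .data$plant,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = paste0(object$period, " (", object$provenance, ")"),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' @export
autoplot.null_distribution <- function(object, ...) {
  df <- tibble::tibble(value = object$replicates)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::geom_vline(xintercept = c(object$q025, object$q975),
                        linetype = "dashed") +
    ggplot2::labs(
      title = sprintf("%s vs %s null: %s", object$metric, object$source_label,
                      object$verdict),
      x = object$metric, y = "replicates"
    ) +
    ggplot2::theme_minimal()
}

#' Annual totals of estimated pollination service
#'
#' @param total Table from [service_total()].
#' @return A ggplot object.
#' @export
plot_service_total <- function(total) {
  ggplot2::ggplot(total, ggplot2::aes(x = .data$year,
                                      y = .data$estimated_grains)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "year", y = "estimated grains deposited") +
    ggplot2::theme_minimal()
}
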