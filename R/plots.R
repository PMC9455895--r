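# ggplot2 views of traces, binarized states, surrogate ensembles and
# metric tables.

#' Plot intensity traces
#'
#' Intensity versus time, one line per ROI, faceted by channel.
#'
#' @param traces Tidy trace tibble (`roi`, `channel`, `frame`,
#'   `intensity`).
#' @return A ggplot object.
#' @export
plot_traces <- function(traces) {
  ggplot2::ggplot(
    traces,
    ggplot2::aes(x = .data$frame, y = .data$intensity, color = .data$roi)
  ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "frame", y = "mean ROI intensity", color = "ROI") +
    ggplot2::theme_minimal()
}

#' Plot binarized state sequences
#'
#' Raster of active/inactive states, ROIs stacked vertically, faceted by
#' channel — the standard visual check that the threshold represents the
#' data.
#'
#' @param states Tidy binary table (`roi`, `channel`, `frame`, `state`).
#' @return A ggplot object.
#' @export
plot_binarized <- function(states) {
  ggplot2::ggplot(
    states,
    ggplot2::aes(x = .data$frame, y = .data$roi, fill = factor(.data$state))
  ) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(ggplot2::vars(.data$channel)) +
    ggplot2::scale_fill_manual(
      values = c(`0` = "grey90", `1` = "grey20"), name = "state"
    ) +
    ggplot2::labs(x = "frame", y = "ROI") +
    ggplot2::theme_minimal()
}

#' Heatmap of a pairwise metric table
#'
#' Sources as rows, targets as columns, fill by value in bits; cells
#' significant at the table's alpha are marked with an asterisk.
#'
#' @param results Tidy result tibble from [pairwise_table()].
#' @param alpha Significance level for the mark (defaults to the alpha
#'   recorded on the table).
#' @return A ggplot object.
#' @export
plot_metric_table <- function(results, alpha = NULL) {
  alpha <- alpha %||% attr(results, "alpha") %||% 0.05
  labels <- attr(results, "labels") %||% unique(c(results$source, results$target))
  d <- results |>
    dplyr::mutate(
      source = factor(.data$source, levels = rev(labels)),
      target = factor(.data$target, levels = labels),
      mark = !is.na(.data$p_value) & .data$p_value < alpha
    )
  ggplot2::ggplot(
    d, ggplot2::aes(x = .data$target, y = .data$source, fill = .data$value_bits)
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(
      ggplot2::aes(label = ifelse(.data$mark, "*", "")), size = 6
    ) +
    ggplot2::scale_fill_viridis_c(name = "bits") +
    ggplot2::labs(
      x = "target ROI", y = "source ROI",
      title = toupper(results$metric[1]),
      subtitle = sprintf("* p < %g (frame-permutation surrogates)", alpha)
    ) +
    ggplot2::theme_minimal()
}

#' Histogram of a surrogate ensemble with the observed value marked
#'
#' @param object An `infoflow_surrogate_test` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.infoflow_surrogate_test <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value_bits)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", color = "white") +
    ggplot2::geom_vline(xintercept = object$value_bits, color = "red") +
    ggplot2::labs(
      x = "surrogate value (bits)", y = "count",
      title = sprintf(
        "%s = %.3f bits, p = %.3g", toupper(object$metric),
        object$value_bits, object$p_value
      )
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
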