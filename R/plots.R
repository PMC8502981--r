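#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   facet_wrap labs theme_minimal scale_colour_manual
#' @export
ggplot2::autoplot

#' Plot a voltage series
#'
#' Line plot of the voltage trace, with the stimulus channel overlaid when
#' present.
#'
#' @param series A series tibble.
#' @param show_stimulus Overlay the stimulus channel.
#' @return A ggplot object.
#' @export
plot_series <- function(series, show_stimulus = TRUE) {
  check_series(series)
  p <- ggplot(series, aes(x = .data$time, y = .data$voltage)) +
    geom_line(linewidth = 0.3) +
    labs(x = "time (ms)", y = "voltage (normalized)") +
    theme_minimal()
  if (show_stimulus && "stimulus" %in% names(series)) {
    p <- p + geom_line(aes(y = .data$stimulus), colour = "firebrick",
                       linewidth = 0.2)
  }
  p
}

#' Plot a forecast against the test data
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object overlaying predicted and true test voltage.
#' @export
autoplot.eval_report <- function(x, ...) {
  df <- bind_rows(
    mutate(x$test[, c("time", "voltage")], trace = "test data"),
    mutate(x$predictions, trace = "prediction")
  )
  ggplot(df, aes(x = .data$time, y = .data$voltage,
                 colour = .data$trace)) +
    geom_line(linewidth = 0.35) +
    scale_colour_manual(values = c(`test data` = "black",
                                   prediction = "#D55E00")) +
    labs(x = "time (ms)", y = "voltage (normalized)",
         title = sprintf("%s closed-loop forecast (RMSE %.4f)",
                         x$forecaster, x$rmse),
         colour = NULL) +
    theme_minimal()
}

#' Plot per-beat APD prediction errors
#'
#' @param report An `eval_report`.
#' @return A ggplot bar chart of absolute APD error by beat.
#' @export
plot_apd_errors <- function(report) {
  stopifnot(inherits(report, "eval_report"))
  df <- tidy(report)
  ggplot(df[df$matched, ], aes(x = .data$beat, y = .data$abs_error)) +
    geom_col(fill = "#0072B2") +
    labs(x = "test beat", y = "absolute APD error (ms)",
         title = report$forecaster) +
    theme_minimal()
}

#' Plot a method-by-size comparison table
#'
#' @param comparison Output of [compare_methods()].
#' @param metric Column to plot (`"rmse_mean"` or `"apd_mae"`).
#' @return A ggplot object, one line per method across network sizes.
#' @export
plot_comparison <- function(comparison, metric = "rmse_mean") {
  ggplot(comparison,
         aes(x = .data$n_neurons, y = .data[[metric]],
             colour = .data$method)) +
    geom_line() + geom_point() +
    labs(x = "network size", y = metric) +
    theme_minimal()
}
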