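# Diagnostic plots. All return ggplot objects.

#' Plot one trial of a cleaning result
#'
#' Raw trial, estimated blanking landmarks and the cleaned trace.
#'
#' @param result a `loglira_result` from [loglira_clean()].
#' @param raw the original [recording()].
#' @param stims the [stim_train()] used for cleaning.
#' @param trial trial index.
#' @param window_ms time span after the onset to display.
#' @return a ggplot object.
#' @export
plot_trial <- function(result, raw, stims, trial = 1L, window_ms = 50) {
  fs <- raw$fs
  on <- as.integer(stims)[trial]
  n <- min(ms_to_samples(window_ms, fs), length(raw$samples) - on + 1L)
  idx <- on:(on + n - 1L)
  t_ms <- (idx - on) / fs * 1e3
  df <- tibble::tibble(
    t_ms = rep(t_ms, 2),
    uv = c(raw$samples[idx], result$recording$samples[idx]),
    trace = rep(c("raw", "clean"), each = length(idx)))
  fit <- result$fits[trial, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_ms, y = .data$uv,
                                   colour = .data$trace)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = fit$beta_ms, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = fit$n_e / fs * 1e3, linetype = "dotted") +
    ggplot2::labs(x = "time after stimulus (ms)", y = "voltage (uV)",
                  colour = NULL,
                  title = sprintf("trial %d: blanking %.2f ms", trial,
                                  fit$beta_ms)) +
    ggplot2::theme_minimal()
}

#' Plot a post-stimulus time histogram
#'
#' @param h a tibble from [psth()].
#' @return a ggplot object.
#' @export
plot_psth <- function(h) {
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_start_ms, y = .data$count)) +
    ggplot2::geom_col(width = min(diff(h$bin_start_ms)), fill = "grey30") +
    ggplot2::labs(x = "latency (ms)", y = "spike count") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.benchmark_report <- function(object, metric = "c0", ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$suppressor, y = .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
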