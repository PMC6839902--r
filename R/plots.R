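# ggplot2 visualisations for the main result types

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a power spectrum
#'
#' @param object A `power_spectrum`.
#' @param xlim Optional frequency range in Hz.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.power_spectrum <- function(object, xlim = NULL, ...) {
  d <- tidy(object)
  if (!is.null(xlim)) d <- d[d$freq >= xlim[1] & d$freq <= xlim[2], ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$freq, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)",
                  y = expression("Power density (" * mu * V^2 / Hz * ")")) +
    ggplot2::theme_minimal()
}

#' Plot a coherence spectrum
#'
#' @param object A `coherence_spectrum`.
#' @param xlim Optional frequency range in Hz.
#' @param ... Unused.
#' @export
autoplot.coherence_spectrum <- function(object, xlim = NULL, ...) {
  d <- tidy(object)
  if (!is.null(xlim)) d <- d[d$freq >= xlim[1] & d$freq <= xlim[2], ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$freq, y = .data$msc)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Frequency (Hz)", y = "Coherence") +
    ggplot2::theme_minimal()
}

#' Plot a spectrogram
#'
#' @param object A `spectrogram`.
#' @param fmax Upper frequency limit in Hz (default 40).
#' @param ... Unused.
#' @export
autoplot.spectrogram <- function(object, fmax = 40, ...) {
  d <- tidy(object)
  d <- d[d$freq <= fmax, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$freq,
                                  fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = expression(mu * V^2 / Hz)) +
    ggplot2::labs(x = "Time (s)", y = "Frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot a differential spectrogram
#'
#' @param object A `diff_spectrogram`.
#' @param fmax Upper frequency limit in Hz (default 40).
#' @param ... Unused.
#' @export
autoplot.diff_spectrogram <- function(object, fmax = 40, ...) {
  d <- tidy(object)
  d <- d[d$freq <= fmax, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$freq,
                                  fill = .data$percent_increase)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(name = "% increase") +
    ggplot2::labs(x = "Time from light onset (s)", y = "Frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot the average trace around light onset
#'
#' @param trials An `aligned_trials` object.
#' @param filtered Apply the zero-phase theta bandpass before
#'   averaging.
#' @return A ggplot with the light epoch shaded.
#' @export
plot_average_trace <- function(trials, filtered = FALSE) {
  d <- average_trace(trials, filtered = filtered)
  dur <- ncol(trials$during) / trials$fs
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::annotate("rect", xmin = 0, xmax = dur, ymin = -Inf, ymax = Inf,
                      alpha = 0.15, fill = "blue") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time from light onset (s)",
                  y = expression("LFP (" * mu * V * ")")) +
    ggplot2::theme_minimal()
}

#' Plot a current-clamp sweep
#'
#' @param sweep A `sweep` tibble.
#' @return A ggplot of the voltage trace with the step window shaded.
#' @export
plot_sweep <- function(sweep) {
  w <- .sweep_window(sweep)
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$t, y = .data$v)) +
    ggplot2::annotate("rect", xmin = w[1], xmax = w[2], ymin = -Inf,
                      ymax = Inf, alpha = 0.1, fill = "orange") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = "Membrane potential (mV)") +
    ggplot2::theme_minimal()
}
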