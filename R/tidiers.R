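# broom-style tidiers for the package's result objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a power spectrum
#'
#' @param x A `power_spectrum`.
#' @param ... Unused.
#' @return A plain tibble with `freq` and `density`.
#' @export
tidy.power_spectrum <- function(x, ...) {
  tibble::tibble(freq = x$freq, density = x$density)
}

#' Glance at a power spectrum
#'
#' @param x A `power_spectrum`.
#' @param ... Unused.
#' @return One-row tibble: `df`, `n_tapers`, `nw`, `n_trials`,
#'   `total_power`.
#' @export
glance.power_spectrum <- function(x, ...) {
  tibble::tibble(
    df = attr(x, "df"),
    n_tapers = attr(x, "n_tapers"),
    nw = attr(x, "nw"),
    n_trials = attr(x, "n_trials"),
    total_power = sum(x$density) * attr(x, "df")
  )
}

#' Tidy a coherence spectrum
#'
#' @param x A `coherence_spectrum`.
#' @param ... Unused.
#' @export
tidy.coherence_spectrum <- function(x, ...) {
  tibble::tibble(freq = x$freq, msc = x$msc)
}

#' Tidy a spectrogram into long format
#'
#' @param x A `spectrogram`.
#' @param ... Unused.
#' @return Tibble with `time`, `freq`, `power`.
#' @export
tidy.spectrogram <- function(x, ...) {
  tibble::tibble(
    time = rep(x$time, each = length(x$freq)),
    freq = rep(x$freq, times = length(x$time)),
    power = as.vector(x$power)
  )
}

#' Tidy a differential spectrogram into long format
#'
#' @param x A `diff_spectrogram`.
#' @param ... Unused.
#' @return Tibble with `time`, `freq`, `percent_increase`.
#' @export
tidy.diff_spectrogram <- function(x, ...) {
  tibble::tibble(
    time = rep(x$time, each = length(x$freq)),
    freq = rep(x$freq, times = length(x$time)),
    percent_increase = as.vector(x$percent_increase)
  )
}

#' Tidy an aligned trial set
#'
#' @param x An `aligned_trials` object.
#' @param ... Unused.
#' @return Long tibble with `trial`, `window` (pre/during), `time`
#'   (s relative to light onset), `value` (µV).
#' @export
tidy.aligned_trials <- function(x, ...) {
  npre <- ncol(x$pre)
  ndur <- ncol(x$during)
  dplyr::bind_rows(
    tibble::tibble(
      trial = rep(x$trial_index, each = npre),
      window = "pre",
      time = rep((seq_len(npre) - npre - 1) / x$fs, times = nrow(x$pre)),
      value = as.vector(t(x$pre))
    ),
    tibble::tibble(
      trial = rep(x$trial_index, each = ndur),
      window = "during",
      time = rep((seq_len(ndur) - 1) / x$fs, times = nrow(x$during)),
      value = as.vector(t(x$during))
    )
  )
}

#' Glance at an aligned trial set
#'
#' @param x An `aligned_trials` object.
#' @param ... Unused.
#' @export
glance.aligned_trials <- function(x, ...) {
  tibble::tibble(
    animal_id = x$animal_id,
    genotype = x$genotype,
    location = x$location,
    stim_freq = x$stim_freq,
    n_trials = nrow(x$pre),
    fs = x$fs
  )
}
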