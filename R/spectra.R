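# Multitaper power spectra, trial averaging, coherence, band powers,
# the theta/delta state ratio, moving-window spectrograms, and the
# zero-phase theta bandpass.
#
# Conventions: densities are one-sided (0..fs/2) in units^2/Hz with
# interior bins doubled, so summing density * df over the whole axis
# returns the mean squared signal (Parseval).  No zero padding by
# default, giving df = fs/n; an `nfft` argument pads and changes the
# bin centers, and is recorded in the output.

.new_spectrum <- function(freq, density, fs, df, n_tapers, nw, n_trials,
                          class2 = "power_spectrum") {
  out <- tibble::tibble(freq = freq, density = density)
  class(out) <- c(class2, class(out))
  attr(out, "fs") <- fs
  attr(out, "df") <- df
  attr(out, "n_tapers") <- n_tapers
  attr(out, "nw") <- nw
  attr(out, "n_trials") <- n_trials
  out
}

# per-taper two-sided eigenspectra -> one-sided mean density
.mt_onesided <- function(x, fs, tapers, nfft = NULL) {
  n <- length(x)
  if (is.null(nfft)) nfft <- n
  stopifnot(nfft >= n)
  V <- tapers$tapers
  k <- ncol(V)
  acc <- numeric(nfft)
  for (j in seq_len(k)) {
    xt <- V[, j] * x
    if (nfft > n) xt <- c(xt, numeric(nfft - n))
    acc <- acc + Mod(stats::fft(xt))^2
  }
  two_sided <- acc / (k * fs)
  nh <- nfft %/% 2 + 1
  one <- two_sided[seq_len(nh)]
  if (nfft %% 2 == 0) {
    if (nh > 2) one[2:(nh - 1)] <- 2 * one[2:(nh - 1)]
  } else {
    if (nh > 1) one[2:nh] <- 2 * one[2:nh]
  }
  list(freq = (seq_len(nh) - 1) * fs / nfft, density = one, df = fs / nfft)
}

#' Multitaper power spectral density of a single segment
#'
#' Averages the eigenspectra of `x` windowed by each Slepian taper.
#' The density is one-sided, in `units^2/Hz`, normalised so that
#' `sum(density) * df` equals the mean squared value of the tapered
#' signal (Parseval).
#'
#' @param x Numeric sample series; its length must equal `tapers$n`.
#' @param fs Sampling rate in Hz.
#' @param tapers A [compute_tapers()] `taper_set`.
#' @param nfft Optional FFT length for zero padding (default: no
#'   padding, `df = fs / length(x)`).
#' @return A `power_spectrum` tibble with columns `freq` (Hz) and
#'   `density` (units^2/Hz), and attributes `fs`, `df`, `n_tapers`,
#'   `nw`, `n_trials`.
#' @examples
#' fs <- 1000
#' t <- seq(0, 3 - 1 / fs, by = 1 / fs)
#' spec <- multitaper_psd(sin(2 * pi * 7 * t), fs, compute_tapers(3000, 1.5, 2))
#' bandpower(spec, c(6, 8)) # ~ 0.5 = A^2/2
#' @export
multitaper_psd <- function(x, fs, tapers, nfft = NULL) {
  stopifnot(inherits(tapers, "taper_set"))
  if (length(x) != tapers$n) {
    stop(sprintf(
      "length(x) = %d but tapers were computed for n = %d samples",
      length(x), tapers$n
    ))
  }
  r <- .mt_onesided(as.numeric(x), fs, tapers, nfft)
  .new_spectrum(r$freq, r$density, fs, r$df, tapers$k, tapers$nw, 1L)
}

#' Trial-averaged multitaper power spectrum
#'
#' Computes the multitaper PSD of every row of `trials` and returns the
#' arithmetic mean across trials.
#'
#' @param trials Numeric matrix, one trial per row; row length must
#'   equal `tapers$n`.
#' @inheritParams multitaper_psd
#' @return A `power_spectrum` tibble; `n_trials` records the number of
#'   trials averaged.
#' @export
trial_psd <- function(trials, fs, tapers, nfft = NULL) {
  trials <- .as_trial_matrix(trials)
  if (nrow(trials) < 1) stop("at least one trial is required")
  stopifnot(inherits(tapers, "taper_set"))
  if (ncol(trials) != tapers$n) {
    stop(sprintf(
      "trials have %d samples but tapers were computed for n = %d",
      ncol(trials), tapers$n
    ))
  }
  acc <- NULL
  for (i in seq_len(nrow(trials))) {
    r <- .mt_onesided(trials[i, ], fs, tapers, nfft)
    acc <- if (is.null(acc)) r$density else acc + r$density
  }
  .new_spectrum(r$freq, acc / nrow(trials), fs, r$df, tapers$k, tapers$nw,
                nrow(trials))
}

.as_trial_matrix <- function(trials) {
  if (is.data.frame(trials)) trials <- as.matrix(trials)
  if (is.vector(trials)) trials <- matrix(trials, nrow = 1)
  stopifnot(is.matrix(trials), is.numeric(trials))
  trials
}

# tapered DFTs for all trials: array [freq, taper, trial] (complex)
.taper_dfts <- function(trials, tapers, nfft) {
  n <- ncol(trials)
  V <- tapers$tapers
  out <- array(complex(1), dim = c(nfft %/% 2 + 1, tapers$k, nrow(trials)))
  nh <- nfft %/% 2 + 1
  for (i in seq_len(nrow(trials))) {
    for (j in seq_len(tapers$k)) {
      xt <- V[, j] * trials[i, ]
      if (nfft > n) xt <- c(xt, numeric(nfft - n))
      out[, j, i] <- stats::fft(xt)[seq_len(nh)]
    }
  }
  out
}

#' Trial-averaged magnitude-squared coherence between two channels
#'
#' Pools tapered cross- and auto-spectra over tapers and trials:
#' `msc = |mean(X * Conj(Y))|^2 / (mean|X|^2 * mean|Y|^2)`.
#'
#' @param x_trials,y_trials Numeric trial-by-sample matrices with
#'   matching dimensions (paired trials).
#' @inheritParams multitaper_psd
#' @return A `coherence_spectrum` tibble with columns `freq` and `msc`
#'   (in `[0, 1]`), and the usual spectral attributes.
#' @export
trial_coherence <- function(x_trials, y_trials, fs, tapers, nfft = NULL) {
  x_trials <- .as_trial_matrix(x_trials)
  y_trials <- .as_trial_matrix(y_trials)
  if (!all(dim(x_trials) == dim(y_trials))) {
    stop("x and y trial matrices must have identical dimensions")
  }
  stopifnot(inherits(tapers, "taper_set"))
  if (ncol(x_trials) != tapers$n) {
    stop(sprintf(
      "trials have %d samples but tapers were computed for n = %d",
      ncol(x_trials), tapers$n
    ))
  }
  n <- ncol(x_trials)
  if (is.null(nfft)) nfft <- n
  X <- .taper_dfts(x_trials, tapers, nfft)
  Y <- .taper_dfts(y_trials, tapers, nfft)
  sxy <- apply(X * Conj(Y), 1, mean)
  sxx <- apply(Mod(X)^2, 1, mean)
  syy <- apply(Mod(Y)^2, 1, mean)
  msc <- Mod(sxy)^2 / (sxx * syy)
  msc[!is.finite(msc)] <- 0
  msc <- pmin(pmax(msc, 0), 1)
  out <- tibble::tibble(
    freq = (seq_len(nfft %/% 2 + 1) - 1) * fs / nfft,
    msc = msc
  )
  class(out) <- c("coherence_spectrum", class(out))
  attr(out, "fs") <- fs
  attr(out, "df") <- fs / nfft
  attr(out, "n_tapers") <- tapers$k
  attr(out, "nw") <- tapers$nw
  attr(out, "n_trials") <- nrow(x_trials)
  out
}

#' Integrated band power of a power spectrum
#'
#' Sums `density * df` over the frequency bins whose centres lie in the
#' closed interval `[band[1], band[2]]`.
#'
#' @param spec A `power_spectrum` from [multitaper_psd()] or
#'   [trial_psd()].
#' @param band Length-2 numeric, band edges in Hz (`lo < hi`).
#' @return Band power in signal units squared.
#' @export
bandpower <- function(spec, band) {
  stopifnot(is.numeric(band), length(band) == 2, band[1] < band[2])
  df <- attr(spec, "df")
  sel <- spec$freq >= band[1] & spec$freq <= band[2]
  if (!any(sel)) {
    stop(sprintf(
      "band [%g, %g] Hz contains no frequency bins (df = %g Hz)",
      band[1], band[2], df
    ))
  }
  sum(spec$density[sel]) * df
}

# mean coherence over band bins (same bin rule as bandpower)
.band_msc <- function(coh, band) {
  sel <- coh$freq >= band[1] & coh$freq <= band[2]
  if (!any(sel)) {
    stop(sprintf(
      "band [%g, %g] Hz contains no frequency bins (df = %g Hz)",
      band[1], band[2], attr(coh, "df")
    ))
  }
  mean(coh$msc[sel])
}

#' Theta/delta band-power ratio of a segment
#'
#' Brain-state index used to select theta-state trials: multitaper band
#' power in the theta range divided by band power in the delta range.
#'
#' @param x Numeric sample series, at least 2 s long so that the delta
#'   band is resolvable.
#' @param fs Sampling rate in Hz.
#' @param theta,delta Band edges in Hz (defaults 5-12 and 1-3).
#' @param nw,k Taper settings (defaults `nw = 3`, `k = 5`).
#' @return The dimensionless ratio; `Inf` (with a warning) when the
#'   delta band power is zero.
#' @export
theta_delta_ratio <- function(x, fs, theta = c(5, 12), delta = c(1, 3),
                              nw = 3, k = 5) {
  if (length(x) < 2 * fs) {
    stop("segment must be at least 2 s long to resolve the delta band")
  }
  tp <- compute_tapers(length(x), nw, k)
  spec <- multitaper_psd(x, fs, tp)
  th <- bandpower(spec, theta)
  de <- bandpower(spec, delta)
  if (de == 0) {
    warning("zero delta band power; ratio is infinite")
    return(Inf)
  }
  th / de
}

#' Moving-window multitaper spectrogram
#'
#' Multitaper PSD in windows of `window` seconds advanced by `step`
#' seconds; column `j` covers
#' `[(j-1)*step, (j-1)*step + window)` seconds.
#'
#' @param x Numeric sample series.
#' @param fs Sampling rate in Hz.
#' @param window,step Window and step sizes in seconds (defaults 1 and
#'   0.1).
#' @param nw,k Taper settings for the window-length tapers.
#' @return A `spectrogram` object: list with `time` (window centres,
#'   s), `freq` (Hz), `power` (frequency x time matrix, units^2/Hz),
#'   `window`, `step`, `fs`, `nw`, `k`.
#' @export
moving_spectrogram <- function(x, fs, window = 1, step = 0.1, nw = 3, k = 5) {
  n <- length(x)
  nwin <- round(window * fs)
  nstep <- step * fs
  if (n < nwin) {
    stop(sprintf(
      "trace (%g s) is shorter than the window (%g s)", n / fs, window
    ))
  }
  n_cols <- floor((n - nwin) / nstep + 1e-9) + 1
  tp <- compute_tapers(nwin, nw, k)
  pow <- NULL
  centers <- numeric(n_cols)
  for (j in seq_len(n_cols)) {
    i0 <- round((j - 1) * nstep)
    seg <- x[(i0 + 1):(i0 + nwin)]
    r <- .mt_onesided(seg, fs, tp)
    if (is.null(pow)) pow <- matrix(0, length(r$density), n_cols)
    pow[, j] <- r$density
    centers[j] <- (i0 + nwin / 2) / fs
  }
  structure(
    list(time = centers, freq = r$freq, power = pow,
         window = window, step = step, fs = fs, nw = nw, k = k),
    class = "spectrogram"
  )
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf(
    "<spectrogram> %d windows (%g s / %g s step) x %d frequency bins (0-%g Hz)\n",
    length(x$time), x$window, x$step, length(x$freq), max(x$freq)
  ))
  invisible(x)
}

#' Zero-phase theta bandpass filter
#'
#' Even-order FIR bandpass (Hamming window design) applied forward and
#' backward, so the passband phase shift is exactly zero and the output
#' has the same length as the input.  Used for visualising phase
#' alignment of theta oscillations to light delivery.
#'
#' @param x Numeric sample series.
#' @param fs Sampling rate in Hz (> 2 x the band's upper edge).
#' @param band Passband edges in Hz (default theta, 5-12).
#' @param order FIR order (even; default 500 at 1 kHz scales with fs).
#' @return Filtered series, same length as `x`.
#' @export
bandpass_theta <- function(x, fs, band = c(5, 12), order = NULL) {
  stopifnot(length(band) == 2, band[1] < band[2])
  if (band[2] >= fs / 2) {
    stop(sprintf(
      "band upper edge %g Hz is not below the Nyquist frequency %g Hz",
      band[2], fs / 2
    ))
  }
  if (is.null(order)) order <- 2 * floor(fs / 2) # ~1 s of taps: ~3 Hz transition
  if (order %% 2 == 1) order <- order + 1
  h <- signal::fir1(order, band / (fs / 2), type = "pass")
  n <- length(x)
  # forward-backward with symmetric padding to suppress edge transients
  npad <- min(n - 1, 3 * order)
  xp <- c(rev(x[seq_len(npad) + 1]), x, rev(x[(n - npad):(n - 1)]))
  y <- signal::filtfilt(h, xp)
  y[(npad + 1):(npad + n)]
}
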