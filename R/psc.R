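# Light-evoked postsynaptic current classification.
#
# With a high-chloride internal at -60 mV, GABA_A responses are fast
# inward (negative) currents and GABA_B responses slow outward
# (positive) currents.  Classification follows fixed amplitude
# criteria (|deflection| >= 10 pA) with class-specific peak-search
# windows placed around the typical times to peak (fast: ~6 ms; slow:
# ~134 ms).

#' Classify a light-evoked postsynaptic current
#'
#' Baseline is the mean of the 50 ms before light onset.  The fast
#' (GABA_A) peak is the minimum in the 0-50 ms post-onset window; the
#' slow (GABA_B) peak is the maximum in the 50-400 ms window.  An
#' inward deflection of at least `criterion_pa` below baseline is a
#' GABA_A response (taking precedence); an outward deflection of at
#' least `criterion_pa` above baseline is a GABA_B response; otherwise
#' no response.  The 0-63% rise time is measured from the onset of the
#' deflection (last baseline crossing before the peak) to the first
#' crossing of 63% of the peak amplitude.
#'
#' @param trace Numeric current series in pA.
#' @param light_onset Light onset in seconds from the start of `trace`.
#' @param fs Sampling rate in Hz.
#' @param criterion_pa Amplitude criterion in pA (default 10).
#' @param gabaa_window_ms,gabab_window_ms Peak-search windows in ms
#'   after light onset.
#' @param baseline_ms Baseline window before onset in ms (default 50).
#' @return A one-row tibble of class `psc_result`: `response_class`
#'   (`"GABA_A"`, `"GABA_B"`, or `"none"`), `amplitude` (pA, signed),
#'   `time_to_peak` (ms from onset), `rise_time_0_63` (ms; `NA` unless
#'   a GABA_A response).
#' @export
classify_psc <- function(trace, light_onset, fs, criterion_pa = 10,
                         gabaa_window_ms = c(0, 50),
                         gabab_window_ms = c(50, 400),
                         baseline_ms = 50) {
  n <- length(trace)
  onset_i <- round(light_onset * fs) + 1L
  base_n <- round(baseline_ms / 1000 * fs)
  if (onset_i - base_n < 1) {
    stop(sprintf("need %g ms of pre-onset baseline", baseline_ms))
  }
  baseline <- mean(trace[(onset_i - base_n):(onset_i - 1L)])

  win_idx <- function(w_ms) {
    i0 <- onset_i + round(w_ms[1] / 1000 * fs)
    i1 <- min(n, onset_i + round(w_ms[2] / 1000 * fs))
    i0:i1
  }
  a_idx <- win_idx(gabaa_window_ms)
  a_rel <- which.min(trace[a_idx])
  a_peak_i <- a_idx[a_rel]
  a_amp <- trace[a_peak_i] - baseline

  b_idx <- win_idx(gabab_window_ms)
  b_rel <- which.max(trace[b_idx])
  b_peak_i <- b_idx[b_rel]
  b_amp <- trace[b_peak_i] - baseline

  if (a_amp <= -criterion_pa) {
    cls <- "GABA_A"
    amp <- a_amp
    peak_i <- a_peak_i
  } else if (b_amp >= criterion_pa) {
    cls <- "GABA_B"
    amp <- b_amp
    peak_i <- b_peak_i
  } else {
    cls <- "none"
    amp <- if (abs(a_amp) >= abs(b_amp)) a_amp else b_amp
    peak_i <- NA_integer_
  }

  ttp <- if (!is.na(peak_i)) 1000 * (peak_i - onset_i) / fs else NA_real_

  rise <- NA_real_
  if (cls == "GABA_A") {
    defl <- trace[onset_i:a_peak_i] - baseline
    # onset of deflection: last non-negative sample before the peak
    nn <- which(defl >= 0)
    i0 <- if (length(nn)) nn[length(nn)] else 1L
    target <- 0.63 * amp # negative
    after <- which(defl[i0:length(defl)] <= target)
    if (length(after)) {
      rise <- 1000 * (after[1] - 1) / fs
    }
  }

  out <- tibble::tibble(
    response_class = cls,
    amplitude = amp,
    baseline = baseline,
    time_to_peak = ttp,
    rise_time_0_63 = rise
  )
  class(out) <- c("psc_result", class(out))
  out
}

#' Synthesise a biexponential postsynaptic current
#'
#' Convenience generator for validation: a biexponential deflection
#' `(exp(-t/tau_decay) - exp(-t/tau_rise))` scaled to a requested
#' signed peak amplitude at a requested time to peak (the rise time
#' constant is solved numerically from the decay constant).
#'
#' @param peak_pa Signed peak amplitude in pA (negative for inward).
#' @param time_to_peak_ms Time from onset to peak in ms.
#' @param tau_decay_ms Decay time constant in ms.
#' @param duration Trace duration in seconds.
#' @param light_onset Onset in seconds.
#' @param fs Sampling rate in Hz.
#' @param baseline_pa Holding-current baseline in pA.
#' @param noise_sd Additive white noise, pA RMS.
#' @param seed Optional seed for the noise.
#' @return Numeric current trace in pA.
#' @export
synth_psc <- function(peak_pa, time_to_peak_ms, tau_decay_ms = 30,
                      duration = 0.6, light_onset = 0.1, fs = 20000,
                      baseline_pa = 0, noise_sd = 0, seed = NULL) {
  ttp_of <- function(tr) tr * tau_decay_ms / (tau_decay_ms - tr) *
    log(tau_decay_ms / tr)
  tr <- stats::uniroot(function(g) ttp_of(g) - time_to_peak_ms,
                       c(1e-3, tau_decay_ms * 0.999))$root
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  shape <- numeric(length(t))
  rel <- (t - light_onset) * 1000
  on <- rel >= 0
  shape[on] <- exp(-rel[on] / tau_decay_ms) - exp(-rel[on] / tr)
  shape <- shape / max(abs(shape))
  x <- baseline_pa + peak_pa * shape
  if (noise_sd > 0) x <- .with_seed(seed, x + stats::rnorm(length(x), 0, noise_sd))
  x
}
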