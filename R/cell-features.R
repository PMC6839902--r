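# Current-clamp intrinsic-property extraction: spike detection,
# threshold by the zero of the smoothed second derivative, full width
# at half maximum, firing frequency, adaptation ratio, interspike
# interval variability, sweep selection, persistent firing, and input
# resistance.

.sweep_fs <- function(sweep) attr(sweep, "fs")
.sweep_window <- function(sweep) c(attr(sweep, "step_onset"),
                                   attr(sweep, "step_offset"))

#' Detect action potentials in a sweep
#'
#' A spike is an upward `dv/dt` excursion exceeding `dvdt_min`
#' (mV/ms) followed by a local maximum above `peak_min` (mV), with a
#' refractory window of `refractory_ms` between accepted peaks.
#'
#' @param sweep A `sweep` tibble ([new_sweep()]).
#' @param dvdt_min Rate criterion in mV/ms (default 20).
#' @param peak_min Peak criterion in mV (default -10).
#' @param refractory_ms Minimum peak separation in ms (default 1).
#' @return A tibble with one row per spike: `peak_time` (s), `peak_v`
#'   (mV), `peak_index`.  Zero rows when no spike is found.
#' @export
detect_spikes <- function(sweep, dvdt_min = 20, peak_min = -10,
                          refractory_ms = 1) {
  fs <- .sweep_fs(sweep)
  if (fs < 10000) {
    warning(sprintf("sampling rate %g Hz is below the recommended 10 kHz", fs))
  }
  v <- sweep$v
  dvdt <- c(diff(v), 0) * fs / 1000 # mV/ms
  above <- which(dvdt > dvdt_min)
  peaks <- integer(0)
  last_peak_t <- -Inf
  i <- 1
  n <- length(v)
  while (i <= length(above)) {
    start <- above[i]
    # extend to the end of this suprathreshold run
    j <- i
    while (j < length(above) && above[j + 1] <= above[j] + 2) j <- j + 1
    run_end <- above[j]
    # the peak is the first local max at/after the run
    pk <- run_end + 1
    while (pk < n && v[pk + 1] >= v[pk]) pk <- pk + 1
    if (v[pk] > peak_min && (pk - 1) / fs - last_peak_t >= refractory_ms / 1000) {
      peaks <- c(peaks, pk)
      last_peak_t <- (pk - 1) / fs
    }
    i <- j + 1
  }
  tibble::tibble(
    peak_time = sweep$t[peaks],
    peak_v = v[peaks],
    peak_index = peaks
  )
}

#' Spike threshold from the smoothed second derivative
#'
#' The threshold is taken at the last negative-to-positive zero
#' crossing of the locally smoothed second difference of the voltage
#' within a short window before the peak's maximal `dv/dt` — the
#' curvature onset immediately preceding the action potential.  When no
#' crossing exists in the window, the first point exceeding a `dv/dt`
#' criterion is used instead and the result is flagged.
#'
#' @param sweep A `sweep` tibble.
#' @param peak_time Peak time (s) of a detected spike.
#' @param search_ms Pre-peak search window in ms (default 4).
#' @param smooth_ms Width of the local polynomial smoother in ms
#'   (default 0.5, order 3).
#' @param dvdt_fallback Fallback rate criterion in mV/ms.
#' @return A list: `threshold_v` (mV), `threshold_time` (s),
#'   `fallback` (logical).
#' @export
spike_threshold <- function(sweep, peak_time, search_ms = 4,
                            smooth_ms = 0.5, dvdt_fallback = 20) {
  fs <- .sweep_fs(sweep)
  v <- sweep$v
  pk <- which.min(abs(sweep$t - peak_time))
  w0 <- max(1L, pk - round(search_ms * fs / 1000))
  seg <- v[w0:pk]
  if (length(seg) < 7) stop("search window too short for curvature analysis")
  # local least-squares polynomial smoothing of the segment
  fl <- max(5L, round(smooth_ms * fs / 1000))
  if (fl %% 2 == 0) fl <- fl + 1L
  if (fl >= length(seg)) fl <- length(seg) - (1 - length(seg) %% 2) - 2L
  sm <- if (fl >= 5) signal::sgolayfilt(seg, p = 3, n = fl) else seg
  d2 <- c(0, diff(sm, differences = 2), 0) * (fs / 1000)^2 # mV/ms^2
  # restrict to before the maximal dv/dt (the upstroke midpoint)
  d1 <- c(diff(sm), 0) * fs / 1000
  lim <- which.max(d1)
  cross <- which(d2[seq_len(max(lim - 1, 1))] <= 0 &
                   d2[seq_len(max(lim - 1, 1)) + 1] > 0)
  if (length(cross)) {
    idx <- w0 + cross[length(cross)] # sample after the crossing
    list(threshold_v = v[idx], threshold_time = sweep$t[idx],
         fallback = FALSE)
  } else {
    above <- which(d1 > dvdt_fallback)
    idx <- if (length(above)) w0 + above[1] - 1L else w0
    list(threshold_v = v[idx], threshold_time = sweep$t[idx],
         fallback = TRUE)
  }
}

#' Action-potential full width at half maximum
#'
#' Width of the spike at `threshold_v + amplitude / 2`, with linear
#' interpolation between samples on both flanks.
#'
#' @param sweep A `sweep` tibble.
#' @param peak_time Spike peak time in s.
#' @param threshold_v Spike threshold in mV.
#' @return Half-width in ms, or `NA` (with attribute `flagged = TRUE`)
#'   when a flank never recrosses the half-maximum level.
#' @export
spike_half_width <- function(sweep, peak_time, threshold_v) {
  fs <- .sweep_fs(sweep)
  v <- sweep$v
  pk <- which.min(abs(sweep$t - peak_time))
  half <- threshold_v + (v[pk] - threshold_v) / 2
  max_ms <- 10
  lim <- round(max_ms * fs / 1000)
  # rising flank: last sample before the peak below the half level
  lo <- max(1L, pk - lim)
  pre <- v[lo:pk]
  below <- which(pre < half)
  hi <- min(length(v), pk + lim)
  post <- v[pk:hi]
  below_post <- which(post < half)
  if (!length(below) || !length(below_post)) {
    out <- NA_real_
    attr(out, "flagged") <- TRUE
    return(out)
  }
  i1 <- below[length(below)] # pre[i1] < half <= pre[i1+1]
  t_up <- (lo - 1 + i1 - 1 + (half - pre[i1]) / (pre[i1 + 1] - pre[i1])) / fs
  i2 <- below_post[1] # post[i2-1] >= half > post[i2]
  t_dn <- (pk - 1 + i2 - 2 + (v[pk - 1 + i2 - 1] - half) /
             (v[pk - 1 + i2 - 1] - v[pk + i2 - 1])) / fs
  1000 * (t_dn - t_up)
}

#' Firing frequency of a sweep
#'
#' Number of action potentials divided by the current-step duration.
#'
#' @param sweep A `sweep` tibble.
#' @param spikes Optional pre-computed [detect_spikes()] result.
#' @return Firing frequency in Hz.
#' @export
firing_frequency <- function(sweep, spikes = NULL) {
  if (is.null(spikes)) spikes <- detect_spikes(sweep)
  w <- .sweep_window(sweep)
  dur <- w[2] - w[1]
  stopifnot(dur > 0)
  in_step <- spikes$peak_time >= w[1] & spikes$peak_time < w[2]
  sum(in_step) / dur
}

#' Adaptation ratio of an interspike-interval sequence
#'
#' `1 - first ISI / last ISI` from the sweep that elicited the maximal
#' firing frequency.  Zero for constant trains; approaches 1 for
#' strongly adapting trains.
#'
#' @param isis Numeric vector of interspike intervals (ms).
#' @return Dimensionless ratio, or flagged `NA` with fewer than 2 ISIs.
#' @export
adaptation_ratio <- function(isis) {
  if (length(isis) < 2) {
    out <- NA_real_
    attr(out, "flagged") <- TRUE
    return(out)
  }
  1 - isis[1] / isis[length(isis)]
}

#' Coefficient of variation of interspike intervals
#'
#' `100 * sd / mean` using the sample (n-1) standard deviation, for the
#' ISIs of the maximal-firing sweep.
#'
#' @param isis Numeric vector of interspike intervals (ms).
#' @return CV in percent, or flagged `NA` with fewer than 2 ISIs.
#' @export
cv_isi <- function(isis) {
  if (length(isis) < 2) {
    out <- NA_real_
    attr(out, "flagged") <- TRUE
    return(out)
  }
  100 * stats::sd(isis) / mean(isis)
}

#' Select the near-threshold and maximal-firing sweeps
#'
#' The near-threshold sweep is the first current step producing more
#' than two action potentials; the maximal-firing sweep is the first
#' step achieving the maximum spike count.
#'
#' @param spike_counts Integer vector of spike counts per ascending
#'   current step.
#' @return A list with `near_threshold` and `max_firing` indices
#'   (`NA` when undefined).
#' @export
select_analysis_sweeps <- function(spike_counts) {
  stopifnot(length(spike_counts) >= 1)
  nt <- which(spike_counts > 2)
  mx <- if (max(spike_counts) > 0) {
    which(spike_counts == max(spike_counts))[1]
  } else NA_integer_
  list(
    near_threshold = if (length(nt)) nt[1] else NA_integer_,
    max_firing = mx
  )
}

#' Detect persistent (barrage) firing across repeated current steps
#'
#' @param repeat_sweeps List of `sweep` tibbles from the repeated
#'   (50% duty cycle) protocol.
#' @param required_repeats Number of repeats needed to call a negative
#'   result (default 100).
#' @return `"yes"` if any spike occurs in an off-phase window, `"no"`
#'   after at least `required_repeats` spike-free off phases,
#'   `"indeterminate"` otherwise.
#' @export
detect_persistent_firing <- function(repeat_sweeps, required_repeats = 100) {
  for (sw in repeat_sweeps) {
    w <- .sweep_window(sw)
    spk <- detect_spikes(sw)
    if (any(spk$peak_time >= w[2] | spk$peak_time < w[1])) return("yes")
  }
  if (length(repeat_sweeps) >= required_repeats) "no" else "indeterminate"
}

#' Input resistance from subthreshold hyperpolarizing sweeps
#'
#' Steady-state voltage deflection (mean over the last 100 ms of the
#' step, relative to the pre-step baseline) regressed on injected
#' current through the origin.  Sweeps containing spikes are rejected
#' from the fit.
#'
#' @param sweeps List of `sweep` tibbles (typically the hyperpolarizing
#'   part of the ladder).
#' @param steady_ms Steady-state window before step offset, ms.
#' @return Input resistance in MΩ (`NA` when no usable sweep).
#' @export
input_resistance <- function(sweeps, steady_ms = 100) {
  dv <- numeric(0)
  ii <- numeric(0)
  for (sw in sweeps) {
    w <- .sweep_window(sw)
    fs <- .sweep_fs(sw)
    I <- sw$i_cmd[which(sw$t >= w[1] & sw$t < w[2])[1]]
    if (nrow(detect_spikes(sw)) > 0) {
      message("sweep with spikes rejected from the input-resistance fit")
      next
    }
    if (is.na(I) || I >= 0) next
    base <- mean(sw$v[sw$t < w[1]])
    steady <- mean(sw$v[sw$t >= w[2] - steady_ms / 1000 & sw$t < w[2]])
    dv <- c(dv, steady - base)
    ii <- c(ii, I)
  }
  if (!length(dv)) return(NA_real_)
  # slope in mV/pA -> GΩ; report MΩ
  1000 * sum(dv * ii) / sum(ii^2)
}

#' Extract the full intrinsic-feature battery of a cell
#'
#' Runs spike detection and every per-spike and per-sweep measure over
#' a current-step ladder (plus, optionally, the repeated protocol for
#' persistent firing), and assembles the one-row-per-cell feature
#' table: resting potential, input resistance, threshold (first spike
#' of the smallest suprathreshold current), firing frequencies near
#' threshold and at maximum, adaptation ratio and ISI variability of
#' the maximal-firing sweep, spike amplitudes and half-widths
#' (threshold-to-peak reference, averaged within the selected sweep),
#' and the persistent-firing call.
#'
#' @param sweeps List of `sweep` tibbles ordered by ascending step
#'   current.
#' @param repeat_sweeps Optional list of repeat-protocol sweeps.
#' @param cell_id Identifier copied into the output.
#' @return A one-row tibble of class `cell_features`.
#' @export
build_cell_features <- function(sweeps, repeat_sweeps = NULL,
                                cell_id = "cell01") {
  stopifnot(length(sweeps) >= 1)
  spk <- lapply(sweeps, detect_spikes)
  counts <- vapply(spk, nrow, integer(1))
  sel <- select_analysis_sweeps(counts)

  first_sw <- sweeps[[1]]
  w <- .sweep_window(first_sw)
  v_rest <- mean(first_sw$v[first_sw$t < w[1]])

  r_in <- input_resistance(sweeps[counts == 0])

  # threshold: first spike elicited by the smallest current
  thr_v <- NA_real_
  first_spiking <- which(counts > 0)
  if (length(first_spiking)) {
    s <- first_spiking[1]
    thr <- spike_threshold(sweeps[[s]], spk[[s]]$peak_time[1])
    thr_v <- thr$threshold_v
  }

  sweep_stats <- function(idx) {
    if (is.na(idx) || counts[idx] == 0) {
      return(list(ff = NA_real_, amp = NA_real_, hw = NA_real_,
                  isis = numeric(0)))
    }
    sw <- sweeps[[idx]]
    events <- spk[[idx]]
    amps <- hws <- numeric(0)
    for (r in seq_len(nrow(events))) {
      th <- spike_threshold(sw, events$peak_time[r])
      amps <- c(amps, events$peak_v[r] - th$threshold_v)
      hw <- spike_half_width(sw, events$peak_time[r], th$threshold_v)
      if (!is.na(hw)) hws <- c(hws, hw)
    }
    list(
      ff = firing_frequency(sw, events),
      amp = mean(amps),
      hw = if (length(hws)) mean(hws) else NA_real_,
      isis = if (nrow(events) >= 2) diff(events$peak_time) * 1000 else numeric(0)
    )
  }
  near <- sweep_stats(sel$near_threshold)
  maxf <- sweep_stats(sel$max_firing)

  persistent <- if (!is.null(repeat_sweeps) && length(repeat_sweeps)) {
    detect_persistent_firing(repeat_sweeps)
  } else "indeterminate"

  out <- tibble::tibble(
    cell_id = cell_id,
    v_rest = v_rest,
    input_resistance = r_in,
    threshold_v = thr_v,
    ff_near_threshold = near$ff,
    ff_max = maxf$ff,
    adaptation_ratio = as.numeric(adaptation_ratio(maxf$isis)),
    cv_isi = as.numeric(cv_isi(maxf$isis)),
    amp_at_threshold = near$amp,
    amp_at_max = maxf$amp,
    hw_at_threshold = near$hw,
    hw_at_max = maxf$hw,
    persistent_firing = persistent
  )
  class(out) <- c("cell_features", class(out))
  out
}
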