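# In-vivo analysis chain: align LFP trials to light onsets, reject
# movement-artifact trials by the range rule, select theta-state
# trials, and quantify power change, coherence change, dominant theta
# frequency, averaged traces, and differential spectrograms.

#' Align an LFP recording into pre/during light trials
#'
#' Cuts a `pre`-second window before and a `during`-second window from
#' each light onset.  Onsets whose windows fall outside the recording
#' are dropped (with a message).
#'
#' @param recording An [lfp_recording()].
#' @param onsets Numeric vector of light-onset times in seconds
#'   (sorted).
#' @param stim_freq Stimulation frequency in Hz, carried into the
#'   results.
#' @param pre,during Window lengths in seconds (defaults 3 and 3).
#' @return An object of class `aligned_trials`: matrices `pre` and
#'   `during` (trial by sample), `fs`, `trial_index` (positions in
#'   `onsets`), `onsets`, and the recording metadata.
#' @export
build_trials <- function(recording, onsets, stim_freq = NA_real_,
                         pre = 3, during = 3) {
  stopifnot(inherits(recording, "lfp_recording"))
  stopifnot(!is.unsorted(onsets))
  fs <- recording$fs
  n <- length(recording$samples)
  npre <- round(pre * fs)
  ndur <- round(during * fs)
  i0 <- round(onsets * fs) # onset sample, 0-based
  ok <- (i0 - npre) >= 0 & (i0 + ndur) <= n
  if (!all(ok)) {
    message(sprintf("dropped %d onset(s) with truncated windows", sum(!ok)))
  }
  if (!any(ok)) stop("no usable onsets: every window falls outside the recording")
  keep <- which(ok)
  pre_m <- t(vapply(i0[keep], function(s) {
    recording$samples[(s - npre + 1):s]
  }, numeric(npre)))
  dur_m <- t(vapply(i0[keep], function(s) {
    recording$samples[(s + 1):(s + ndur)]
  }, numeric(ndur)))
  structure(
    list(pre = pre_m, during = dur_m, fs = fs,
         trial_index = keep, onsets = onsets[keep],
         animal_id = recording$animal_id, genotype = recording$genotype,
         location = recording$location, stim_freq = stim_freq),
    class = "aligned_trials"
  )
}

#' @export
print.aligned_trials <- function(x, ...) {
  cat(sprintf(
    "<aligned_trials> %s %s %s: %d trials, %g s pre + %g s during @ %g Hz%s\n",
    x$animal_id, x$genotype, x$location, nrow(x$pre),
    ncol(x$pre) / x$fs, ncol(x$during) / x$fs, x$fs,
    if (!is.na(x$stim_freq)) sprintf(", stim %g Hz", x$stim_freq) else ""
  ))
  invisible(x)
}

.subset_trials <- function(trials, rows) {
  trials$pre <- trials$pre[rows, , drop = FALSE]
  trials$during <- trials$during[rows, , drop = FALSE]
  trials$trial_index <- trials$trial_index[rows]
  trials$onsets <- trials$onsets[rows]
  trials
}

#' Reject movement-artifact trials by the range rule
#'
#' Each trial's trace is the concatenated pre + during window; its
#' range is the maximum minus the minimum value.  The threshold —
#' `multiplier` times the mean range over all input trials — is
#' computed once, and trials whose range exceeds it are removed in a
#' single pass.
#'
#' @param trials An `aligned_trials` object with at least 2 trials.
#' @param multiplier Threshold multiplier on the mean range
#'   (default 2).
#' @return A list: `kept` (`aligned_trials`) and `report` (tibble of
#'   class `trial_qc`: per-trial `range`, `removed` flag, with
#'   `mean_range` and `threshold` attributes).
#' @export
reject_artifact_trials <- function(trials, multiplier = 2) {
  stopifnot(inherits(trials, "aligned_trials"))
  if (nrow(trials$pre) < 2) stop("at least 2 trials are required for QC")
  full <- cbind(trials$pre, trials$during)
  rng <- apply(full, 1, function(r) max(r) - min(r))
  mean_range <- mean(rng)
  threshold <- multiplier * mean_range
  removed <- rng > threshold
  if (all(removed)) stop("the range rule removed every trial")
  report <- tibble::tibble(
    trial = trials$trial_index,
    range = rng,
    removed = removed
  )
  class(report) <- c("trial_qc", class(report))
  attr(report, "mean_range") <- mean_range
  attr(report, "threshold") <- threshold
  list(kept = .subset_trials(trials, which(!removed)), report = report)
}

#' Select theta-state trials by the pre-window theta/delta ratio
#'
#' The ratio is computed on the 3 s window before light delivery only;
#' trials with ratio strictly greater than `criterion` are selected.
#'
#' @param trials An `aligned_trials` object (after QC).
#' @param criterion Ratio criterion (default 4.5, strict `>`).
#' @param nw,k Taper settings for the ratio's band powers.
#' @return A tibble of class `theta_selection`: per-trial `ratio` and
#'   `selected` flag (row order matches the trials).
#' @export
select_theta_trials <- function(trials, criterion = 4.5, nw = 3, k = 5) {
  stopifnot(inherits(trials, "aligned_trials"))
  ratios <- apply(trials$pre, 1, theta_delta_ratio, fs = trials$fs,
                  nw = nw, k = k)
  selected <- ratios > criterion
  if (!any(selected)) {
    warning("no trial exceeds the theta criterion; selection is empty")
  }
  out <- tibble::tibble(
    trial = trials$trial_index,
    ratio = ratios,
    selected = selected
  )
  class(out) <- c("theta_selection", class(out))
  attr(out, "criterion") <- criterion
  out
}

.change_result <- function(trials, baseline, light, measure) {
  if (baseline <= 0) stop("baseline value is zero; percent change undefined")
  out <- tibble::tibble(
    animal_id = trials$animal_id,
    genotype = trials$genotype,
    location = trials$location,
    stim_freq = trials$stim_freq,
    measure = measure,
    baseline_value = baseline,
    light_value = light,
    percent_change = 100 * (light - baseline) / baseline
  )
  class(out) <- c("change_result", class(out))
  out
}

#' Percent change in band power at the stimulation frequency
#'
#' Band power in the 1 Hz band centred on the stimulation frequency is
#' computed per trial for the pre (baseline) and during (light)
#' windows, averaged across trials, and the light value expressed as a
#' percent change over baseline.
#'
#' The default tapers are band-matched: time-bandwidth `nw = 1.5` over
#' a 3 s window gives a spectral half-bandwidth of 0.5 Hz, so the
#' analysis band spans the full main lobe and a spectral line at the
#' stimulation frequency is recovered without leakage loss.
#'
#' @param trials An `aligned_trials` object with `stim_freq` set.
#' @param halfwidth Band half-width in Hz (default 0.5).
#' @param nw,k Taper settings (defaults 1.5 and 2).
#' @return A one-row `change_result` tibble.
#' @export
power_change_at_stim <- function(trials, halfwidth = 0.5, nw = 1.5, k = 2) {
  stopifnot(inherits(trials, "aligned_trials"))
  if (is.na(trials$stim_freq)) stop("stim_freq is not set on these trials")
  if (nrow(trials$pre) < 1) stop("at least one trial is required")
  f <- trials$stim_freq
  band <- c(f - halfwidth, f + halfwidth)
  tp <- compute_tapers(ncol(trials$pre), nw, k)
  bp <- function(m) {
    vapply(seq_len(nrow(m)), function(i) {
      bandpower(multitaper_psd(m[i, ], trials$fs, tp), band)
    }, numeric(1))
  }
  baseline <- mean(bp(trials$pre))
  light <- mean(bp(trials$during))
  .change_result(trials, baseline, light, "bandpower")
}

#' Percent change in interregional coherence at the stimulation
#' frequency
#'
#' Trial-averaged magnitude-squared coherence between two channels is
#' computed separately for the pre and during windows over the trials
#' common to both channels (post-QC intersection); the value is the
#' mean coherence over the bins within ±`halfwidth` Hz of the
#' stimulation frequency, and the change is a percent increase from
#' baseline.
#'
#' @param hi,tt `aligned_trials` for the two channels (same onsets).
#' @param halfwidth Band half-width in Hz (default 0.5).
#' @param nw,k Taper settings (defaults 1.5 and 2).
#' @return A one-row `change_result` tibble (metadata from `hi`;
#'   `location` set to `"HI-TT"`).
#' @export
coherence_change_at_stim <- function(hi, tt, halfwidth = 0.5,
                                     nw = 1.5, k = 2) {
  stopifnot(inherits(hi, "aligned_trials"), inherits(tt, "aligned_trials"))
  if (is.na(hi$stim_freq)) stop("stim_freq is not set on these trials")
  common <- intersect(hi$trial_index, tt$trial_index)
  if (length(common) < 2) stop("fewer than 2 trials common to both channels")
  hi <- .subset_trials(hi, match(common, hi$trial_index))
  tt <- .subset_trials(tt, match(common, tt$trial_index))
  f <- hi$stim_freq
  band <- c(f - halfwidth, f + halfwidth)
  tp <- compute_tapers(ncol(hi$pre), nw, k)
  base <- .band_msc(trial_coherence(hi$pre, tt$pre, hi$fs, tp), band)
  light <- .band_msc(trial_coherence(hi$during, tt$during, hi$fs, tp), band)
  res <- .change_result(hi, base, light, "coherence")
  res$location <- "HI-TT"
  res
}

#' Dominant frequency within the theta band
#'
#' Argmax of the trial-averaged multitaper PSD over the theta range,
#' refined by three-point parabolic interpolation around the peak bin.
#' Ties break to the lower frequency (logged); a flat spectrum returns
#' the value with a low-confidence flag.
#'
#' @param trials An `aligned_trials` object.
#' @param window `"pre"` or `"during"`.
#' @param band Theta band in Hz (default 5-12).
#' @param nw,k Taper settings.
#' @return A numeric frequency in Hz with attributes `low_confidence`
#'   and `tie`.
#' @export
dominant_theta_frequency <- function(trials, window = c("pre", "during"),
                                     band = c(5, 12), nw = 3, k = 5) {
  stopifnot(inherits(trials, "aligned_trials"))
  window <- match.arg(window)
  m <- if (window == "pre") trials$pre else trials$during
  if (nrow(m) < 1) stop("at least one trial is required")
  tp <- compute_tapers(ncol(m), nw, k)
  spec <- trial_psd(m, trials$fs, tp)
  sel <- which(spec$freq >= band[1] & spec$freq <= band[2])
  d <- spec$density[sel]
  tie <- FALSE
  flat <- diff(range(d)) == 0
  pk_rel <- which(d == max(d))
  if (length(pk_rel) > 1) {
    tie <- TRUE
    message("tied spectral peaks; returning the lower frequency")
  }
  pk <- sel[pk_rel[1]]
  df <- attr(spec, "df")
  f0 <- spec$freq[pk]
  # parabolic refinement using linear neighbours
  if (!flat && pk > 1 && pk < nrow(spec)) {
    y1 <- spec$density[pk - 1]
    y2 <- spec$density[pk]
    y3 <- spec$density[pk + 1]
    denom <- y1 - 2 * y2 + y3
    if (denom < 0) {
      delta <- 0.5 * (y1 - y3) / denom
      f0 <- f0 + max(-0.5, min(0.5, delta)) * df
    }
  }
  out <- f0
  attr(out, "low_confidence") <- flat
  attr(out, "tie") <- tie
  out
}

#' Trial-averaged LFP trace around light onset
#'
#' Pointwise mean across trials of the concatenated pre + during
#' window, optionally theta-bandpass filtered (zero phase) per trial
#' before averaging.
#'
#' @param trials An `aligned_trials` object.
#' @param filtered If `TRUE`, apply [bandpass_theta()] to each trial
#'   first.
#' @return A tibble with columns `time` (s, 0 = light onset) and
#'   `value` (µV).
#' @export
average_trace <- function(trials, filtered = FALSE) {
  stopifnot(inherits(trials, "aligned_trials"))
  if (nrow(trials$pre) < 1) stop("at least one trial is required")
  full <- cbind(trials$pre, trials$during)
  if (filtered) {
    full <- t(apply(full, 1, bandpass_theta, fs = trials$fs))
  }
  avg <- colMeans(full)
  npre <- ncol(trials$pre)
  tibble::tibble(
    time = (seq_along(avg) - npre - 1) / trials$fs,
    value = avg
  )
}

#' Differential (percent-increase) spectrogram
#'
#' Trial-averaged moving spectrograms are computed for the pre and
#' during windows; the pre-window power is averaged over time per
#' frequency bin to form the baseline vector, and the during-window
#' spectrogram is expressed as a percent increase over that baseline,
#' per bin.
#'
#' @param trials An `aligned_trials` object.
#' @param window,step Spectrogram window and step in seconds (defaults
#'   1 and 0.1).
#' @param nw,k Taper settings for the window-length tapers.
#' @return A list of class `diff_spectrogram`: `time` (s from light
#'   onset), `freq` (Hz), `percent_increase` (frequency x time),
#'   `baseline` (per-frequency baseline power), and `flagged_bins`
#'   (frequencies with zero baseline, excluded from maxima).
#' @export
differential_spectrogram <- function(trials, window = 1, step = 0.1,
                                     nw = 3, k = 5) {
  stopifnot(inherits(trials, "aligned_trials"))
  n_tr <- nrow(trials$pre)
  if (n_tr < 1) stop("at least one trial is required")
  avg_sgram <- function(m) {
    acc <- NULL
    for (i in seq_len(n_tr)) {
      sg <- moving_spectrogram(m[i, ], trials$fs, window, step, nw, k)
      acc <- if (is.null(acc)) sg$power else acc + sg$power
    }
    sg$power <- acc / n_tr
    sg
  }
  pre_sg <- avg_sgram(trials$pre)
  dur_sg <- avg_sgram(trials$during)
  baseline <- rowMeans(pre_sg$power)
  flagged <- which(baseline <= 0)
  pct <- sweep(dur_sg$power, 1, baseline, "/") * 100 - 100
  if (length(flagged)) pct[flagged, ] <- NA_real_
  structure(
    list(time = dur_sg$time, freq = dur_sg$freq, percent_increase = pct,
         baseline = baseline, flagged_bins = dur_sg$freq[flagged],
         window = window, step = step),
    class = "diff_spectrogram"
  )
}

#' @export
print.diff_spectrogram <- function(x, ...) {
  cat(sprintf(
    "<diff_spectrogram> %d windows x %d frequency bins; max increase %.1f%% at %g Hz\n",
    length(x$time), length(x$freq),
    max(x$percent_increase, na.rm = TRUE),
    x$freq[which.max(apply(x$percent_increase, 1, max, na.rm = TRUE))]
  ))
  invisible(x)
}

#' Per-genotype and stimulation-frequency summary of change results
#'
#' Groups per-animal percent changes by genotype and stimulation
#' frequency, reporting mean, standard deviation, standard error and
#' n — a table ready for external inferential testing.
#'
#' @param results A data frame of `change_result` rows (one per animal
#'   x frequency).
#' @return A tibble, one row per genotype x frequency x measure.
#' @export
genotype_summary <- function(results) {
  results <- tibble::as_tibble(results)
  stopifnot(nrow(results) >= 1)
  results |>
    dplyr::group_by(.data$genotype, .data$stim_freq, .data$measure) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_change = mean(.data$percent_change),
      sd_change = stats::sd(.data$percent_change),
      sem_change = stats::sd(.data$percent_change) / sqrt(dplyr::n()),
      .groups = "drop"
    )
}
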