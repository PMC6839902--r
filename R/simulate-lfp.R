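# Synthetic two-channel LFP sessions with ground truth.
#
# The generator emulates the statistical structure the in-vivo analyses
# assume: a 1/f background, alternating theta (quasi-sinusoid near
# 7.6 Hz) and non-theta (delta-dominated) brain states with exponential
# dwell times, optogenetic entrainment during light epochs (an additive
# sinusoid at the stimulation frequency, phase-locked to pulse onsets,
# with band power equal to entrainment_gain times the expected baseline
# band power in the same 1 Hz band), a second channel that mixes in a
# share of the first, and occasional high-amplitude movement artifacts.

#' Parameters for the synthetic LFP session generator
#'
#' @param sampling_rate Hz (default 1000).
#' @param session_duration Total session length in seconds; `NULL`
#'   derives it from the stimulation schedule.
#' @param theta_freq Theta oscillation frequency in Hz (default 7.6).
#' @param theta_amp Theta amplitude in µV (present during theta
#'   states).
#' @param delta_amp Delta-oscillation amplitude in µV (present during
#'   non-theta states, at `delta_freq`).
#' @param delta_freq Hz, centre of the non-theta slow oscillation.
#' @param noise_exponent Spectral exponent alpha of the 1/f^alpha
#'   background.
#' @param noise_scale Square root of the background PSD at 1 Hz, in
#'   µV/sqrt(Hz).
#' @param phase_diffusion Phase-diffusion rate of the oscillatory
#'   components in rad^2/s; sets the linewidth of the theta peak.
#' @param mean_theta_dwell,mean_nontheta_dwell Mean dwell times of the
#'   two brain states, in seconds.
#' @param entrainment_gain Fractional band-power increase at the
#'   stimulation frequency during light; 0 emulates an opsin-negative
#'   animal.
#' @param phase_reset If `TRUE`, the entrained component is phase-locked
#'   to each light-pulse onset; if `FALSE` its phase is random per
#'   epoch.
#' @param tt_coupling Share of the hippocampal signal mixed into the
#'   second (tenia tecta) channel, in `[0, 1]`.
#' @param artifact_prob Per-trial probability of a movement artifact.
#' @param artifact_amp Artifact amplitude in µV (square transient,
#'   200 ms).
#' @param seed Integer seed; identical parameters and seed give
#'   bit-identical sessions.
#' @return A list of class `lfp_sim_params`.
#' @export
lfp_sim_params <- function(sampling_rate = 1000,
                           session_duration = NULL,
                           theta_freq = 7.6,
                           theta_amp = 60,
                           delta_amp = 40,
                           delta_freq = 2,
                           noise_exponent = 1,
                           noise_scale = 10,
                           phase_diffusion = 0.9,
                           mean_theta_dwell = 30,
                           mean_nontheta_dwell = 30,
                           entrainment_gain = 1,
                           phase_reset = TRUE,
                           tt_coupling = 0.5,
                           artifact_prob = 0.1,
                           artifact_amp = 2000,
                           seed = 1L) {
  stopifnot(sampling_rate > 0, theta_amp >= 0, delta_amp >= 0,
            noise_scale >= 0, entrainment_gain >= 0,
            artifact_prob >= 0, artifact_prob <= 1,
            tt_coupling >= 0, tt_coupling <= 1,
            mean_theta_dwell > 0, mean_nontheta_dwell > 0)
  structure(as.list(environment()), class = "lfp_sim_params")
}

#' Light-delivery protocol
#'
#' Describes the stimulation schedule: pulse width, pulse period (by
#' default one pulse per cycle of the stimulation frequency), epoch
#' length, inter-epoch interval (onset to onset), and the list of
#' stimulation frequencies delivered in randomly assigned order.
#'
#' @param frequencies Stimulation frequencies in Hz.
#' @param pulse_width Pulse duration in seconds (default 0.005).
#' @param period Pulse period in seconds; `NULL` means `1/frequency`.
#' @param epoch_duration Light-on epoch length in seconds (default 3).
#' @param inter_epoch Interval between epoch onsets in seconds
#'   (default 30).
#' @param n_epochs_per_freq Number of epochs delivered at each
#'   frequency (default 20).
#' @param order_seed Seed for the random frequency order.
#' @return A list of class `stim_protocol` with a `duty_cycle` field in
#'   percent (for explicit `period` only).
#' @export
stim_protocol <- function(frequencies = 7,
                          pulse_width = 0.005,
                          period = NULL,
                          epoch_duration = 3,
                          inter_epoch = 30,
                          n_epochs_per_freq = 20,
                          order_seed = 1L) {
  stopifnot(length(frequencies) >= 1, all(frequencies > 0),
            pulse_width > 0, epoch_duration > 0,
            epoch_duration < inter_epoch)
  if (!is.null(period) && pulse_width >= period) {
    stop("pulse_width must be smaller than the pulse period")
  }
  duty_cycle <- if (!is.null(period)) 100 * pulse_width / period else NA_real_
  structure(
    list(frequencies = frequencies, pulse_width = pulse_width,
         period = period, epoch_duration = epoch_duration,
         inter_epoch = inter_epoch, n_epochs_per_freq = n_epochs_per_freq,
         order_seed = order_seed, duty_cycle = duty_cycle),
    class = "stim_protocol"
  )
}

# schedule: onset seconds + frequency for every epoch
.build_schedule <- function(protocol, session_duration, lead_in = 5) {
  n_epochs <- length(protocol$frequencies) * protocol$n_epochs_per_freq
  onsets <- lead_in + (seq_len(n_epochs) - 1) * protocol$inter_epoch
  needed <- onsets + protocol$epoch_duration + lead_in
  if (!is.null(session_duration)) {
    bad <- which(needed > session_duration)
    if (length(bad)) {
      stop(sprintf(
        "session of %g s is too short: epoch %d (onset %g s) does not fit",
        session_duration, bad[1], onsets[bad[1]]
      ))
    }
  } else {
    session_duration <- max(needed)
  }
  freq_order <- .with_seed(protocol$order_seed, {
    unlist(lapply(seq_len(protocol$n_epochs_per_freq), function(i) {
      protocol$frequencies[sample.int(length(protocol$frequencies))]
    }))
  })
  list(
    schedule = tibble::tibble(
      trial = seq_len(n_epochs),
      onset = onsets,
      frequency = freq_order
    ),
    session_duration = session_duration
  )
}

# expected baseline band power in [f - hw, f + hw] at stim frequency f
.expected_baseline_bandpower <- function(params, f, hw = 0.5) {
  p_theta <- params$mean_theta_dwell /
    (params$mean_theta_dwell + params$mean_nontheta_dwell)
  bg <- stats::integrate(
    function(g) .background_psd(g, params$noise_scale, params$noise_exponent),
    f - hw, f + hw
  )$value
  th <- p_theta * params$theta_amp^2 / 2 *
    .lorentzian_band_fraction(params$theta_freq, f - hw, f + hw,
                              params$phase_diffusion)
  de <- (1 - p_theta) * params$delta_amp^2 / 2 *
    .lorentzian_band_fraction(params$delta_freq, f - hw, f + hw,
                              params$phase_diffusion)
  bg + th + de
}

#' Simulate a two-channel LFP session with ground truth
#'
#' Generates hippocampal (`HI`) and tenia tecta (`TT`) channels over a
#' stimulation schedule, with state labels, injected artifacts, and
#' entrainment epochs fully recorded in the returned ground truth.
#'
#' During light epochs of an opsin-positive session
#' (`entrainment_gain > 0`) a sinusoid at the scheduled stimulation
#' frequency is added to the hippocampal channel.  Its amplitude is
#' calibrated so that its power equals `entrainment_gain` times the
#' expected baseline band power in the 1 Hz band centred on the
#' stimulation frequency, so the expected percent power change
#' recovered downstream is `100 * entrainment_gain`.
#'
#' @param params An [lfp_sim_params()] object.
#' @param protocol A [stim_protocol()] object.
#' @param animal_id Identifier stored in the recording metadata.
#' @return A list of class `lfp_session` with elements `hi` and `tt`
#'   ([lfp_recording()] objects), `events` (tibble: trial, onset s,
#'   frequency Hz), and `truth` (list: `state_labels` logical
#'   per-sample theta flags, `artifact_trials`, `entrainment_epochs`
#'   tibble, `entrainment_gain`, per-frequency entrainment amplitudes).
#' @export
simulate_lfp_session <- function(params, protocol, animal_id = "sim01") {
  stopifnot(inherits(params, "lfp_sim_params"),
            inherits(protocol, "stim_protocol"))
  max_f <- max(protocol$frequencies)
  if (params$sampling_rate <= 2 * max_f) {
    stop("sampling_rate must exceed twice the highest stimulation frequency")
  }
  sched <- .build_schedule(protocol, params$session_duration)
  fs <- params$sampling_rate
  n <- round(sched$session_duration * fs)
  genotype <- if (params$entrainment_gain > 0) "opsin+" else "opsin-"

  out <- .with_seed(params$seed, {
    t <- (seq_len(n) - 1) / fs

    # brain-state process: alternating exponential dwells
    labels <- logical(n)
    state_theta <- stats::runif(1) < params$mean_theta_dwell /
      (params$mean_theta_dwell + params$mean_nontheta_dwell)
    i <- 1L
    while (i <= n) {
      mu <- if (state_theta) params$mean_theta_dwell else params$mean_nontheta_dwell
      len <- max(1L, round(stats::rexp(1, 1 / mu) * fs))
      j <- min(n, i + len - 1L)
      labels[i:j] <- state_theta
      state_theta <- !state_theta
      i <- j + 1L
    }

    # oscillatory components with slowly diffusing phase
    step_sd <- sqrt(params$phase_diffusion / fs)
    th_phase <- 2 * pi * params$theta_freq * t +
      cumsum(stats::rnorm(n, 0, step_sd)) + stats::runif(1, 0, 2 * pi)
    de_phase <- 2 * pi * params$delta_freq * t +
      cumsum(stats::rnorm(n, 0, step_sd)) + stats::runif(1, 0, 2 * pi)
    osc <- ifelse(labels,
                  params$theta_amp * sin(th_phase),
                  params$delta_amp * sin(de_phase))

    hi <- .one_over_f_noise(n, fs, params$noise_scale,
                            params$noise_exponent) + osc

    # entrainment during light epochs
    amp_by_freq <- vapply(
      sort(unique(sched$schedule$frequency)),
      function(f) sqrt(2 * params$entrainment_gain *
                         .expected_baseline_bandpower(params, f)),
      numeric(1)
    )
    names(amp_by_freq) <- as.character(sort(unique(sched$schedule$frequency)))
    ent <- numeric(n)
    if (params$entrainment_gain > 0) {
      for (r in seq_len(nrow(sched$schedule))) {
        onset <- sched$schedule$onset[r]
        f <- sched$schedule$frequency[r]
        i0 <- round(onset * fs) + 1L
        i1 <- min(n, round((onset + protocol$epoch_duration) * fs))
        tt_loc <- (seq(i0, i1) - i0) / fs
        phase0 <- if (params$phase_reset) 0 else stats::runif(1, 0, 2 * pi)
        ent[i0:i1] <- amp_by_freq[as.character(f)] *
          sin(2 * pi * f * tt_loc + phase0)
      }
    }
    hi <- hi + ent

    # second channel: coupled share of HI plus independent background
    tt_ch <- params$tt_coupling * hi +
      sqrt(max(0, 1 - params$tt_coupling^2)) *
      .one_over_f_noise(n, fs, params$noise_scale, params$noise_exponent)

    # movement artifacts: square transients hitting both electrodes
    artifact_trials <- integer(0)
    art_len <- round(0.2 * fs)
    for (r in seq_len(nrow(sched$schedule))) {
      if (stats::runif(1) < params$artifact_prob) {
        artifact_trials <- c(artifact_trials, sched$schedule$trial[r])
        onset <- sched$schedule$onset[r]
        lo <- round((onset - 3) * fs) + 1L
        hi_idx <- round((onset + protocol$epoch_duration) * fs)
        start <- sample(lo:(hi_idx - art_len), 1)
        sel <- start:(start + art_len - 1L)
        hi[sel] <- hi[sel] + params$artifact_amp
        tt_ch[sel] <- tt_ch[sel] + params$artifact_amp
      }
    }

    list(hi = hi, tt = tt_ch, labels = labels,
         artifact_trials = artifact_trials, amp_by_freq = amp_by_freq)
  })

  truth <- list(
    state_labels = out$labels,
    artifact_trials = out$artifact_trials,
    entrainment_epochs = tibble::tibble(
      trial = sched$schedule$trial,
      start = sched$schedule$onset,
      end = sched$schedule$onset + protocol$epoch_duration,
      frequency = sched$schedule$frequency
    ),
    entrainment_gain = params$entrainment_gain,
    entrainment_amp = out$amp_by_freq
  )

  structure(
    list(
      hi = lfp_recording(out$hi, fs, animal_id, genotype, "HI"),
      tt = lfp_recording(out$tt, fs, animal_id, genotype, "TT"),
      events = sched$schedule,
      truth = truth,
      params = params,
      protocol = protocol
    ),
    class = "lfp_session"
  )
}

#' Construct an LFP recording object
#'
#' @param samples Numeric sample series in µV.
#' @param fs Sampling rate in Hz.
#' @param animal_id Animal identifier.
#' @param genotype `"opsin+"` or `"opsin-"`.
#' @param location Electrode location, `"HI"` or `"TT"`.
#' @return A list of class `lfp_recording`.
#' @export
lfp_recording <- function(samples, fs, animal_id, genotype, location) {
  stopifnot(is.numeric(samples), length(samples) > 0, fs > 0)
  genotype <- match.arg(genotype, c("opsin+", "opsin-"))
  location <- match.arg(location, c("HI", "TT"))
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs),
         animal_id = animal_id,
         genotype = genotype, location = location, units = "uV"),
    class = "lfp_recording"
  )
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf(
    "<lfp_recording> %s %s %s: %d samples @ %g Hz (%.1f s)\n",
    x$animal_id, x$genotype, x$location, length(x$samples), x$fs,
    length(x$samples) / x$fs
  ))
  invisible(x)
}

#' @export
print.lfp_session <- function(x, ...) {
  cat(sprintf(
    "<lfp_session> %s (%s): %.0f s, %d stimulation epochs at %s Hz\n",
    x$hi$animal_id, x$hi$genotype, length(x$hi$samples) / x$hi$fs,
    nrow(x$events), paste(sort(unique(x$events$frequency)), collapse = "/")
  ))
  invisible(x)
}
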