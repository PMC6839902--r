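# Parametric current-clamp sweeps with analytically known spike
# features, so the feature-extraction battery can be validated by
# parameter recovery.
#
# Spike template (piecewise, analytically invertible):
#   linear approach  : plateau -> threshold over `ramp_ms`
#   exponential rise : threshold -> peak over `rise_ms` (tau = rise/3)
#   linear fall      : peak -> threshold -> AHP minimum
#   exponential AHP  : relaxation back to the plateau
# The fall slope is chosen so the full width at half maximum equals the
# requested half_width exactly.

#' Parameters for the synthetic current-clamp generator
#'
#' @param v_rest Resting membrane potential in mV.
#' @param r_in Input resistance in MΩ.
#' @param threshold_v Spike threshold in mV (must exceed `v_rest`).
#' @param spike_peak Spike peak in mV (must exceed `threshold_v`).
#' @param half_width Action-potential full width at half maximum, ms.
#' @param adaptation_target Adaptation ratio `1 - first/last` interspike
#'   interval realised in the maximal-firing sweep, in `[0, 1)`.
#' @param cv_target Coefficient of variation of the interspike
#'   intervals in the maximal-firing sweep, percent.  Must be at least
#'   the CV implied by the adaptation ramp; the realised value is
#'   recorded in the ground truth.
#' @param persistent If `TRUE`, off-phase spikes appear in the repeat
#'   protocol after `persistent_onset_repeat` repeats.
#' @param sweep_sampling_rate Hz (default 20000).
#' @param step_start First (most hyperpolarized) current step in pA.
#' @param step_size Current-step increment in pA.
#' @param step_duration Step length in seconds (default 0.5).
#' @param n_steps Number of steps in the ladder.
#' @param membrane_tau Passive membrane time constant in seconds.
#' @param ff_gain Firing-rate slope above rheobase, Hz/pA.
#' @param noise_sd Voltage noise, mV RMS.
#' @param persistent_onset_repeat Repeat index at which off-phase
#'   firing begins when `persistent` is set.
#' @param seed Integer seed.
#' @return A list of class `cell_sim_params`.
#' @export
cell_sim_params <- function(v_rest = -60,
                            r_in = 180,
                            threshold_v = -44,
                            spike_peak = 10,
                            half_width = 0.92,
                            adaptation_target = 0.4,
                            cv_target = NULL,
                            persistent = FALSE,
                            sweep_sampling_rate = 20000,
                            step_start = -300,
                            step_size = 50,
                            step_duration = 0.5,
                            n_steps = 17,
                            membrane_tau = 0.02,
                            ff_gain = 0.25,
                            noise_sd = 0.1,
                            persistent_onset_repeat = 60,
                            seed = 1L) {
  stopifnot(threshold_v > v_rest, spike_peak > threshold_v, half_width > 0,
            adaptation_target >= 0, adaptation_target < 1,
            r_in > 0, step_duration > 0, n_steps >= 1)
  structure(as.list(environment()), class = "cell_sim_params")
}

# template timing (ms): returns rise/fall geometry for a target FWHM
.template_geometry <- function(half_width, rise_ms = 0.35) {
  tau <- rise_ms / 3
  # time (before peak) at which the exponential rise passes half max
  t_half_up <- tau * log(1 + 0.5 * (exp(rise_ms / tau) - 1))
  pre_half <- rise_ms - t_half_up # width contributed by the rising flank
  fall_ms <- 2 * (half_width - pre_half)
  if (fall_ms <= 0) {
    stop("half_width too small for the template's rising flank")
  }
  list(rise_ms = rise_ms, tau = tau, fall_ms = fall_ms, pre_half = pre_half)
}

# sample the spike template on a grid (ms, relative to spike onset at 0)
.spike_template <- function(params, fs) {
  geom <- .template_geometry(params$half_width)
  amp <- params$spike_peak - params$threshold_v
  ahp_depth <- 8
  fall_slope <- amp / geom$fall_ms # mV per ms
  ahp_extra_ms <- ahp_depth / fall_slope
  ahp_tau_ms <- 2
  total_ms <- geom$rise_ms + geom$fall_ms + ahp_extra_ms + 6 * ahp_tau_ms
  tms <- seq(0, total_ms, by = 1000 / fs)
  v <- numeric(length(tms))
  rise_sel <- tms <= geom$rise_ms
  v[rise_sel] <- params$threshold_v + amp *
    (exp(tms[rise_sel] / geom$tau) - 1) / (exp(geom$rise_ms / geom$tau) - 1)
  fall_end <- geom$rise_ms + geom$fall_ms + ahp_extra_ms
  fall_sel <- tms > geom$rise_ms & tms <= fall_end
  v[fall_sel] <- params$spike_peak - fall_slope * (tms[fall_sel] - geom$rise_ms)
  ahp_sel <- tms > fall_end
  v[ahp_sel] <- params$threshold_v - ahp_depth *
    exp(-(tms[ahp_sel] - fall_end) / ahp_tau_ms)
  list(v = v, n = length(v), peak_offset_ms = geom$rise_ms,
       total_ms = total_ms)
}

# deterministic ISI design: geometric ramp realising the adaptation
# ratio, with an alternating perturbation of the interior ISIs scaled
# to reach cv_target when it exceeds the ramp-implied CV
.design_isis <- function(n_spikes, available_ms, adaptation, cv_target) {
  m <- n_spikes - 1
  if (m < 1) return(numeric(0))
  if (m == 1) {
    return(available_ms * 0.9)
  }
  ratio <- (1 / (1 - adaptation))^(1 / (m - 1))
  base <- ratio^(0:(m - 1))
  base <- base / sum(base) * available_ms * 0.9
  cv_of <- function(x) 100 * stats::sd(x) / mean(x)
  if (!is.null(cv_target) && m >= 4) {
    ramp_cv <- cv_of(base)
    if (cv_target > ramp_cv) {
      # alternate +/- on interior ISIs; keeps first and last untouched
      pert <- rep(0, m)
      idx <- 2:(m - 1)
      pert[idx] <- rep_len(c(1, -1), length(idx))
      if (sum(pert[idx]) != 0) pert[idx[length(idx)]] <- 0
      f <- function(beta) cv_of(base * (1 + beta * pert)) - cv_target
      upper <- 0.9
      if (f(upper) > 0) {
        beta <- stats::uniroot(f, c(0, upper))$root
        base <- base * (1 + beta * pert)
      }
    }
  }
  base
}

#' Simulate a current-clamp step protocol with ground truth
#'
#' Generates the full sweep ladder plus, when requested, the repeated
#' (50% duty cycle) protocol used to probe persistent firing.  All
#' spike features of the generated sweeps are known exactly and
#' returned as ground truth.
#'
#' @param params A [cell_sim_params()] object.
#' @param n_repeats Number of repeat sweeps for the persistent-firing
#'   protocol (default 100; 0 skips it).
#' @return A list of class `cc_simulation`: `sweeps` (list of `sweep`
#'   tibbles ordered by step current), `repeats` (list of repeat
#'   sweeps), and `truth` (list with every generated feature:
#'   `v_rest`, `r_in`, `threshold_v`, `spike_peak`, `half_width`,
#'   spike counts and times per sweep, realised `adaptation_ratio` and
#'   `cv_isi` of the maximal-firing sweep, `persistent`).
#' @export
simulate_current_clamp <- function(params, n_repeats = 100) {
  stopifnot(inherits(params, "cell_sim_params"))
  fs <- params$sweep_sampling_rate
  if (params$half_width < 4 * 1000 / fs) {
    stop(sprintf(
      "half_width %g ms is below 4 sample intervals (%g ms) and cannot be resolved",
      params$half_width, 4 * 1000 / fs
    ))
  }
  tmpl <- .spike_template(params, fs)
  step_on <- 0.1
  step_off <- step_on + params$step_duration
  sweep_dur <- step_off + 0.15
  nsamp <- round(sweep_dur * fs)
  tvec <- (seq_len(nsamp) - 1) / fs
  currents <- params$step_start + (seq_len(params$n_steps) - 1) * params$step_size
  rheobase <- (params$threshold_v - params$v_rest) / params$r_in * 1000 # pA

  out <- .with_seed(params$seed, {
    sweeps <- vector("list", params$n_steps)
    spike_times <- vector("list", params$n_steps)
    for (s in seq_len(params$n_steps)) {
      I <- currents[s]
      i_cmd <- numeric(nsamp)
      on_sel <- tvec >= step_on & tvec < step_off
      i_cmd[on_sel] <- I
      spiking <- I > rheobase
      # passive response (sub- and suprathreshold share the charging curve,
      # clamped at a depolarized plateau when spiking)
      dv_inf <- I * params$r_in / 1000 # mV
      v <- params$v_rest + dv_inf *
        (1 - exp(-pmax(0, tvec - step_on) / params$membrane_tau))
      v[tvec >= step_off] <- params$v_rest +
        dv_inf * (1 - exp(-params$step_duration / params$membrane_tau)) *
        exp(-(tvec[tvec >= step_off] - step_off) / params$membrane_tau)
      st <- numeric(0)
      if (spiking) {
        plateau <- params$threshold_v - 6
        v[on_sel] <- pmin(v[on_sel], plateau)
        post <- tvec >= step_off
        v[post] <- params$v_rest + (plateau - params$v_rest) *
          exp(-(tvec[post] - step_off) / params$membrane_tau)
        n_spk <- max(1L, round((params$ff_gain * (I - rheobase)) *
                                 params$step_duration))
        first_lat_ms <- 15
        avail_ms <- params$step_duration * 1000 - first_lat_ms - tmpl$total_ms
        isis <- .design_isis(n_spk, avail_ms, params$adaptation_target,
                             params$cv_target)
        onsets_ms <- first_lat_ms + c(0, cumsum(isis))
        st <- step_on + (onsets_ms + tmpl$peak_offset_ms) / 1000
        v <- .insert_spikes(v, fs, step_on, onsets_ms, tmpl, plateau, params)
      }
      spike_times[[s]] <- st
      vn <- v + stats::rnorm(nsamp, 0, params$noise_sd)
      sweeps[[s]] <- new_sweep(tvec, vn, i_cmd, fs, step_on, step_off)
    }

    repeats <- list()
    if (n_repeats > 0) {
      rep_I <- 300
      rep_on <- 0.05
      rep_off <- rep_on + params$step_duration
      rep_dur <- rep_off + params$step_duration # 50% duty cycle
      rn <- round(rep_dur * fs)
      rt <- (seq_len(rn) - 1) / fs
      n_on <- max(1L, round(params$ff_gain * (rep_I - rheobase) *
                              params$step_duration))
      for (r in seq_len(n_repeats)) {
        i_cmd <- numeric(rn)
        i_cmd[rt >= rep_on & rt < rep_off] <- rep_I
        plateau <- params$threshold_v - 6
        v <- rep(params$v_rest, rn)
        v[rt >= rep_on & rt < rep_off] <- plateau
        avail_ms <- params$step_duration * 1000 - 15 - tmpl$total_ms
        isis <- .design_isis(n_on, avail_ms, params$adaptation_target,
                             params$cv_target)
        onsets_ms <- 15 + c(0, cumsum(isis))
        v <- .insert_spikes(v, fs, rep_on, onsets_ms, tmpl, plateau, params)
        if (params$persistent && r >= params$persistent_onset_repeat) {
          off_onsets_ms <- seq(30, params$step_duration * 1000 - tmpl$total_ms,
                               by = 50)
          v <- .insert_spikes(v, fs, rep_off, off_onsets_ms, tmpl,
                              params$v_rest, params)
        }
        v <- v + stats::rnorm(rn, 0, params$noise_sd)
        repeats[[r]] <- new_sweep(rt, v, i_cmd, fs, rep_on, rep_off)
      }
    }
    list(sweeps = sweeps, repeats = repeats, spike_times = spike_times)
  })

  counts <- lengths(out$spike_times)
  sel <- select_analysis_sweeps(counts)
  max_isis <- if (!is.na(sel$max_firing) && counts[sel$max_firing] >= 2) {
    diff(out$spike_times[[sel$max_firing]]) * 1000
  } else numeric(0)
  truth <- list(
    v_rest = params$v_rest,
    r_in = params$r_in,
    threshold_v = params$threshold_v,
    spike_peak = params$spike_peak,
    amplitude = params$spike_peak - params$threshold_v,
    half_width = params$half_width,
    spike_counts = counts,
    spike_times = out$spike_times,
    ff_near_threshold = if (!is.na(sel$near_threshold)) {
      counts[sel$near_threshold] / params$step_duration
    } else NA_real_,
    ff_max = if (!is.na(sel$max_firing)) {
      counts[sel$max_firing] / params$step_duration
    } else NA_real_,
    adaptation_ratio = if (length(max_isis) >= 2) {
      1 - max_isis[1] / max_isis[length(max_isis)]
    } else NA_real_,
    cv_isi = if (length(max_isis) >= 2) {
      100 * stats::sd(max_isis) / mean(max_isis)
    } else NA_real_,
    persistent = params$persistent,
    currents = currents
  )
  structure(list(sweeps = out$sweeps, repeats = out$repeats, truth = truth),
            class = "cc_simulation")
}

# overwrite the membrane trace with spike templates at given onsets
# (ms, relative to `t0` seconds); approach ramp from `plateau`
.insert_spikes <- function(v, fs, t0, onsets_ms, tmpl, plateau, params) {
  ramp_ms <- 1.5
  ramp_n <- round(ramp_ms * fs / 1000)
  for (o in onsets_ms) {
    i0 <- round((t0 + o / 1000) * fs) + 1L
    i1 <- min(length(v), i0 + tmpl$n - 1L)
    if (i0 > length(v)) next
    v[i0:i1] <- tmpl$v[seq_len(i1 - i0 + 1L)]
    r0 <- max(1L, i0 - ramp_n)
    nr <- i0 - r0
    if (nr > 0) {
      v[r0:(i0 - 1L)] <- plateau +
        (params$threshold_v - plateau) * (seq_len(nr) - 1) / nr
    }
  }
  v
}

#' Construct a current-clamp sweep
#'
#' @param t Time vector in seconds.
#' @param v Membrane potential in mV.
#' @param i_cmd Command current in pA.
#' @param fs Sampling rate in Hz.
#' @param step_onset,step_offset Current-step window in seconds.
#' @return A `sweep` tibble with columns `t`, `v`, `i_cmd` and
#'   attributes `fs`, `step_onset`, `step_offset`.
#' @export
new_sweep <- function(t, v, i_cmd, fs, step_onset, step_offset) {
  stopifnot(length(t) == length(v), length(v) == length(i_cmd),
            step_onset >= t[1], step_offset <= t[length(t)] + 1.5 / fs)
  out <- tibble::tibble(t = t, v = v, i_cmd = i_cmd)
  class(out) <- c("sweep", class(out))
  attr(out, "fs") <- fs
  attr(out, "step_onset") <- step_onset
  attr(out, "step_offset") <- step_offset
  out
}
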