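# shared fixtures, built in code

fixture_sine <- function(freq, fs = 1000, dur = 3, amp = 1, phase = 0) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  amp * sin(2 * pi * freq * t + phase)
}

# a recording whose samples are their own 0-based index (for windowing
# arithmetic checks)
fixture_index_recording <- function(n = 20000, fs = 1000) {
  lfp_recording(seq_len(n) - 1, fs, "idx", "opsin+", "HI")
}

# aligned trials built directly from a trial x sample matrix pair
fixture_trials <- function(pre, during, fs = 1000, stim_freq = 7) {
  structure(
    list(pre = pre, during = during, fs = fs,
         trial_index = seq_len(nrow(pre)), onsets = seq_len(nrow(pre)) * 10,
         animal_id = "fix", genotype = "opsin+", location = "HI",
         stim_freq = stim_freq),
    class = "aligned_trials"
  )
}

# small default LFP validation session (compressed epoch spacing)
fixture_session <- function(seed, gain = 1, freq = 18, n_epochs = 20,
                            inter_epoch = 10, ...) {
  simulate_lfp_session(
    lfp_sim_params(entrainment_gain = gain, seed = seed, ...),
    stim_protocol(frequencies = freq, n_epochs_per_freq = n_epochs,
                  inter_epoch = inter_epoch, order_seed = seed)
  )
}
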