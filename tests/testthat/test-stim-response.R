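# trial alignment, QC, theta selection, and the percent-change measures

fs <- 1000

test_that("trial windows use half-open sample arithmetic around the onset", {
  rec <- fixture_index_recording()
  tr <- build_trials(rec, onsets = 10, stim_freq = 7)
  # samples are their own 0-based index: pre = [7000, 10000), during = [10000, 13000)
  expect_equal(as.numeric(tr$pre[1, ]), 7000:9999)
  expect_equal(as.numeric(tr$during[1, ]), 10000:12999)
})

test_that("onsets with truncated windows are dropped and counted", {
  rec <- fixture_index_recording()
  expect_message(tr <- build_trials(rec, onsets = c(1, 10, 19.5), stim_freq = 7),
                 "dropped 2")
  expect_equal(nrow(tr$pre), 1)
  expect_equal(tr$trial_index, 2L)
  expect_error(build_trials(rec, onsets = 0.5), "no usable onsets")
})

test_that("every scheduled epoch of a well-formed session yields a trial", {
  ses <- fixture_session(seed = 50, n_epochs = 25)
  tr <- build_trials(ses$hi, ses$events$onset, stim_freq = 18)
  expect_equal(nrow(tr$pre), 25)
})

test_that("the range rule removes exactly the trials above twice the mean range", {
  # ranges {1 x9, 30}: mean 3.9, threshold 7.8, one removal
  pre <- matrix(0, 10, 100)
  during <- matrix(0, 10, 100)
  pre[, 1] <- 0.5; pre[, 2] <- -0.5 # range 1 for all
  during[10, 1] <- 15; during[10, 2] <- -15 # trial 10 range 30
  tr <- fixture_trials(pre, during, fs = fs)
  qc <- reject_artifact_trials(tr)
  expect_equal(attr(qc$report, "mean_range"), 3.9)
  expect_equal(attr(qc$report, "threshold"), 7.8)
  expect_equal(which(qc$report$removed), 10L)
  expect_equal(nrow(qc$kept$pre), 9)
  # kept + removed partition the input
  expect_setequal(c(qc$kept$trial_index, qc$report$trial[qc$report$removed]),
                  tr$trial_index)
})

test_that("equal ranges remove nothing and degenerate inputs error", {
  m <- matrix(rep(c(-1, 1), 50), 4, 100, byrow = TRUE)
  tr <- fixture_trials(m, m, fs = fs)
  qc <- reject_artifact_trials(tr)
  expect_equal(sum(qc$report$removed), 0)
  one <- fixture_trials(m[1, , drop = FALSE], m[1, , drop = FALSE], fs = fs)
  expect_error(reject_artifact_trials(one), "at least 2")
})

test_that("injected artifacts are recovered exactly by the range rule", {
  ses <- fixture_session(seed = 51, n_epochs = 30)
  tr <- build_trials(ses$hi, ses$events$onset, stim_freq = 18)
  qc <- reject_artifact_trials(tr)
  expect_setequal(qc$report$trial[qc$report$removed], ses$truth$artifact_trials)
})

test_that("theta selection is strict at the criterion and order invariant", {
  ses <- fixture_session(seed = 52, n_epochs = 12)
  tr <- build_trials(ses$hi, ses$events$onset, stim_freq = 18)
  qc <- reject_artifact_trials(tr)
  sel <- select_theta_trials(qc$kept)
  # boundary: a criterion equal to a trial's ratio must NOT select it
  r1 <- sel$ratio[1]
  at_bound <- select_theta_trials(qc$kept, criterion = r1)
  expect_false(at_bound$selected[1])
  just_below <- select_theta_trials(qc$kept, criterion = r1 - 1e-9)
  expect_true(just_below$selected[1])
  # permuting trials permutes, but does not change, the selected set
  perm <- sample(nrow(qc$kept$pre))
  shuffled <- optoephys:::.subset_trials(qc$kept, perm)
  sel_p <- select_theta_trials(shuffled)
  expect_setequal(sel_p$trial[sel_p$selected], sel$trial[sel$selected])
})

test_that("theta selection agrees with ground-truth state labels", {
  agree <- unlist(lapply(1:4, function(s) {
    ses <- fixture_session(seed = 320 + s, n_epochs = 25)
    tr <- build_trials(ses$hi, ses$events$onset, stim_freq = 18)
    qc <- reject_artifact_trials(tr)
    sel <- select_theta_trials(qc$kept)
    labs <- ses$truth$state_labels
    truth <- vapply(qc$kept$onsets, function(on) {
      idx <- (round((on - 3) * fs) + 1):round(on * fs)
      mean(labs[idx]) > 0.5
    }, logical(1))
    sel$selected == truth
  }))
  expect_gte(mean(agree), 0.95)
})

test_that("an all-non-theta session warns of an empty selection", {
  p <- lfp_sim_params(mean_theta_dwell = 1e-3, mean_nontheta_dwell = 1e6,
                      artifact_prob = 0, seed = 53)
  pr <- stim_protocol(frequencies = 18, n_epochs_per_freq = 5, inter_epoch = 10)
  ses <- simulate_lfp_session(p, pr)
  tr <- build_trials(ses$hi, ses$events$onset, stim_freq = 18)
  expect_warning(sel <- select_theta_trials(tr), "empty")
  expect_equal(sum(sel$selected), 0)
})

test_that("power change is zero when light equals baseline and scale invariant", {
  set.seed(54)
  m <- matrix(rnorm(5 * 3000), 5)
  tr <- fixture_trials(m, m, fs = fs, stim_freq = 7)
  pc <- power_change_at_stim(tr)
  expect_equal(pc$percent_change, 0, tolerance = 1e-10)
  # doubling both windows leaves the percent change unchanged
  set.seed(55)
  m2 <- matrix(rnorm(5 * 3000), 5)
  tr_a <- fixture_trials(m, m2, fs = fs, stim_freq = 7)
  tr_b <- fixture_trials(2 * m, 2 * m2, fs = fs, stim_freq = 7)
  expect_equal(power_change_at_stim(tr_a)$percent_change,
               power_change_at_stim(tr_b)$percent_change, tolerance = 1e-9)
})

test_that("adding a sinusoid with band power equal to baseline gives +100%", {
  set.seed(56)
  m <- matrix(rnorm(8 * 3000), 8)
  tr0 <- fixture_trials(m, m, fs = fs, stim_freq = 20)
  base_bp <- power_change_at_stim(tr0)$baseline_value
  amp <- sqrt(2 * base_bp)
  s <- fixture_sine(20, amp = amp)
  during <- sweep(m, 2, -s) # m + sinusoid on every trial
  tr1 <- fixture_trials(m, during, fs = fs, stim_freq = 20)
  pc <- power_change_at_stim(tr1)
  expect_equal(pc$percent_change, 100, tolerance = 10)
})

test_that("coherence change is zero for identical channels and needs pairs", {
  set.seed(57)
  m1 <- matrix(rnorm(6 * 3000), 6)
  m2 <- matrix(rnorm(6 * 3000), 6)
  hi <- fixture_trials(m1, m2, fs = fs, stim_freq = 7)
  tt <- fixture_trials(m1, m2, fs = fs, stim_freq = 7)
  cc <- coherence_change_at_stim(hi, tt)
  expect_equal(cc$percent_change, 0, tolerance = 1e-6)
  expect_equal(cc$baseline_value, 1, tolerance = 1e-9)
  lone <- optoephys:::.subset_trials(tt, 1)
  expect_error(coherence_change_at_stim(hi, lone), "fewer than 2")
})

test_that("a shared light-locked component raises coherence; independent channels do not", {
  cc_pos <- vapply(c(58, 61, 62), function(s) {
    ses <- fixture_session(seed = s, gain = 1.5, n_epochs = 25)
    hi <- build_trials(ses$hi, ses$events$onset, stim_freq = 18)
    tt <- build_trials(ses$tt, ses$events$onset, stim_freq = 18)
    qh <- reject_artifact_trials(hi)
    qt <- reject_artifact_trials(tt)
    coherence_change_at_stim(qh$kept, qt$kept)$percent_change
  }, numeric(1))
  expect_gt(mean(cc_pos), 50)
  # without entrainment (opsin-negative) no shared light-locked component
  # is added, and the mean change sits at zero within estimator noise
  cc0 <- vapply(1:6, function(s) {
    ses0 <- fixture_session(seed = 700 + s, gain = 0, n_epochs = 25)
    hi0 <- build_trials(ses0$hi, ses0$events$onset, stim_freq = 18)
    tt0 <- build_trials(ses0$tt, ses0$events$onset, stim_freq = 18)
    q0 <- reject_artifact_trials(hi0)
    qt0 <- reject_artifact_trials(tt0)
    coherence_change_at_stim(q0$kept, qt0$kept)$percent_change
  }, numeric(1))
  expect_lt(abs(mean(cc0)), 40)
  expect_gt(mean(cc_pos), mean(cc0))
})

test_that("dominant theta frequency finds pure tones within half a bin", {
  m <- t(replicate(3, fixture_sine(7.6)))
  tr <- fixture_trials(m, m, fs = fs, stim_freq = 7)
  f <- dominant_theta_frequency(tr, "pre")
  expect_equal(as.numeric(f), 7.6, tolerance = 1 / 3 / 2)
  expect_false(attr(f, "low_confidence"))
})

test_that("a flat spectrum is a logged tie returning the lowest frequency", {
  m <- matrix(0, 2, 3000)
  tr <- fixture_trials(m, m, fs = fs, stim_freq = 7)
  expect_message(f <- dominant_theta_frequency(tr, "pre"), "lower")
  expect_true(attr(f, "tie"))
  expect_true(attr(f, "low_confidence"))
  expect_equal(as.numeric(f), 5, tolerance = 1 / 3)
})

test_that("average trace is the identity for one trial with full length", {
  set.seed(60)
  pre <- matrix(rnorm(3000), 1)
  during <- matrix(rnorm(3000), 1)
  tr <- fixture_trials(pre, during, fs = fs)
  at <- average_trace(tr)
  expect_equal(nrow(at), 6000)
  expect_equal(at$value, c(pre[1, ], during[1, ]))
  expect_equal(at$time[3001], 0)
})

test_that("differential spectrogram is centred on 0 for identical windows", {
  set.seed(61)
  m <- matrix(rnorm(4 * 3000), 4)
  tr <- fixture_trials(m, m, fs = fs, stim_freq = 7)
  ds <- differential_spectrogram(tr)
  expect_length(ds$time, 21)
  # during == pre: each frequency row averages to exactly 0% and every
  # entry stays within moving-window estimator noise
  expect_lt(max(abs(rowMeans(ds$percent_increase))), 1e-8)
  expect_lt(max(abs(ds$percent_increase), na.rm = TRUE), 200)
})

test_that("genotype summary groups per genotype and frequency", {
  res <- dplyr::bind_rows(lapply(1:3, function(i) {
    tibble::tibble(
      animal_id = paste0("a", i), genotype = c("opsin+", "opsin-")[1 + i %% 2],
      location = "HI", stim_freq = 7, measure = "bandpower",
      baseline_value = 1, light_value = 1 + i, percent_change = 100 * i
    )
  }))
  tab <- genotype_summary(res)
  expect_equal(nrow(tab), 2)
  one <- genotype_summary(res[1, ])
  expect_equal(one$mean_change, res$percent_change[1])
  expect_equal(one$n, 1L)
})
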