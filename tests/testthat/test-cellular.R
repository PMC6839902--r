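# current-clamp feature extraction

make_cell <- function(seed, ...) {
  simulate_current_clamp(cell_sim_params(seed = seed, ...), n_repeats = 0)
}

test_that("spike detection finds exactly the generated spikes", {
  sim <- make_cell(70, adaptation_target = 0.3, cv_target = 15)
  counts <- vapply(sim$sweeps, function(sw) nrow(detect_spikes(sw)), integer(1))
  expect_equal(counts, sim$truth$spike_counts)
  # subthreshold sweeps are empty
  expect_equal(sum(counts[sim$truth$currents < 0]), 0)
})

test_that("two spikes 2 ms apart are both detected", {
  p <- cell_sim_params(seed = 71)
  fs <- p$sweep_sampling_rate
  tmpl <- optoephys:::.spike_template(p, fs)
  n <- round(0.2 * fs)
  v <- rep(p$threshold_v - 6, n)
  v <- optoephys:::.insert_spikes(v, fs, 0, c(50, 52), tmpl,
                                  p$threshold_v - 6, p)
  sw <- new_sweep((seq_len(n) - 1) / fs, v, rep(100, n), fs, 0, 0.2)
  expect_equal(nrow(detect_spikes(sw)), 2)
})

test_that("threshold recovery from the curvature onset is within 1 mV", {
  errs <- vapply(1:10, function(s) {
    sim <- make_cell(200 + s, threshold_v = -44, noise_sd = 0.2)
    sw_idx <- which(sim$truth$spike_counts > 0)[1]
    sw <- sim$sweeps[[sw_idx]]
    spk <- detect_spikes(sw)
    th <- spike_threshold(sw, spk$peak_time[1])
    th$threshold_v - (-44)
  }, numeric(1))
  expect_lt(max(abs(errs)), 1)
})

test_that("a spikeless concave charging curve exercises the no-crossing fallback", {
  fs <- 20000
  n <- 2000
  t <- (seq_len(n) - 1) / fs
  v <- -60 + 40 * (1 - exp(-t / 0.005)) # strictly negative curvature
  sw <- new_sweep(t, v, rep(0, n), fs, 0, n / fs)
  th <- spike_threshold(sw, peak_time = t[n])
  expect_true(th$fallback)
})

test_that("half-width follows the geometry of the spike", {
  # symmetric triangular spike, base width 1.0 ms -> FWHM 0.5 ms
  fs <- 100000
  half_n <- round(0.0005 * fs)
  tri <- c(seq(-50, 10, length.out = half_n + 1),
           seq(10, -50, length.out = half_n + 1)[-1])
  v <- c(rep(-50, 200), tri, rep(-50, 200))
  sw <- new_sweep((seq_along(v) - 1) / fs, v, rep(0, length(v)), fs, 0,
                  length(v) / fs)
  pk <- which.max(v)
  hw <- spike_half_width(sw, (pk - 1) / fs, threshold_v = -50)
  expect_equal(hw, 0.5, tolerance = 0.01)
  # the half-max level is threshold + amplitude/2
  expect_equal(-50 + (10 - -50) / 2, -20)
})

test_that("template spikes reproduce the designed FWHM within 2 samples", {
  sim <- make_cell(72, half_width = 0.92)
  sw_idx <- which(sim$truth$spike_counts > 2)[1]
  sw <- sim$sweeps[[sw_idx]]
  spk <- detect_spikes(sw)
  th <- spike_threshold(sw, spk$peak_time[1])
  hw <- spike_half_width(sw, spk$peak_time[1], th$threshold_v)
  expect_equal(hw, 0.92, tolerance = 2 * 1000 / 20000)
})

test_that("an unresolvable half-width is rejected by the generator", {
  expect_error(
    simulate_current_clamp(cell_sim_params(half_width = 0.1, seed = 73)),
    "4 sample intervals"
  )
})

test_that("firing frequency is count over step duration", {
  sim <- make_cell(74)
  counts <- sim$truth$spike_counts
  i10 <- which(counts >= 10)[1]
  sw <- sim$sweeps[[i10]]
  expect_equal(firing_frequency(sw), counts[i10] / 0.5)
  sub <- sim$sweeps[[1]]
  expect_equal(firing_frequency(sub), 0)
})

test_that("adaptation ratio follows its definition", {
  expect_equal(adaptation_ratio(rep(10, 8)), 0)
  expect_equal(adaptation_ratio(c(10, 14, 20)), 0.5)
  expect_equal(adaptation_ratio(c(10, 20, 30)), 1 - 1 / 3, tolerance = 0.005)
  short <- adaptation_ratio(5)
  expect_true(is.na(short))
  expect_true(attr(short, "flagged"))
})

test_that("ISI CV uses the sample standard deviation and is scale invariant", {
  expect_equal(cv_isi(rep(7, 5)), 0)
  isis <- c(8, 12)
  expect_equal(cv_isi(isis), 100 * sd(isis) / mean(isis))
  expect_equal(cv_isi(isis * 10), cv_isi(isis))
  expect_true(is.na(cv_isi(numeric(0))))
})

test_that("sweep selection takes the first qualifying steps", {
  sel <- select_analysis_sweeps(c(0, 1, 3, 5, 8, 8))
  expect_equal(sel$near_threshold, 3L)
  expect_equal(sel$max_firing, 5L)
  expect_true(is.na(select_analysis_sweeps(c(0, 0, 2))$near_threshold))
  both <- select_analysis_sweeps(4)
  expect_equal(both$near_threshold, 1L)
  expect_equal(both$max_firing, 1L)
})

test_that("persistent firing is detected by off-phase spikes with the 100-repeat rule", {
  simy <- simulate_current_clamp(
    cell_sim_params(persistent = TRUE, persistent_onset_repeat = 40, seed = 75),
    n_repeats = 45
  )
  expect_equal(detect_persistent_firing(simy$repeats), "yes")
  simn <- simulate_current_clamp(cell_sim_params(seed = 76), n_repeats = 100)
  expect_equal(detect_persistent_firing(simn$repeats), "no")
  expect_equal(detect_persistent_firing(simn$repeats[1:60]), "indeterminate")
})

test_that("input resistance follows Ohm's law and rejects spiking sweeps", {
  sim <- make_cell(77, r_in = 180)
  sub <- sim$sweeps[sim$truth$currents < 0]
  expect_equal(input_resistance(sub), 180, tolerance = 0.02 * 180)
  # a spiking sweep passed in is rejected from the fit (message + same result)
  with_spiker <- c(sub, sim$sweeps[which(sim$truth$spike_counts > 3)[1]])
  expect_message(r2 <- input_resistance(with_spiker), "rejected")
  expect_equal(r2, input_resistance(sub))
  expect_true(is.na(input_resistance(sim$sweeps[sim$truth$currents > 0][1])))
})

test_that("feature extraction recovers ground truth across cells", {
  set.seed(78)
  n_cells <- 12
  res <- lapply(seq_len(n_cells), function(i) {
    adapt <- runif(1, 0, 0.6)
    hw <- runif(1, 0.6, 1.4)
    sim <- simulate_current_clamp(
      cell_sim_params(seed = 1000 + i, adaptation_target = adapt,
                      cv_target = runif(1, 5, 30), half_width = hw,
                      threshold_v = runif(1, -48, -40),
                      r_in = runif(1, 120, 250)),
      n_repeats = 0
    )
    feat <- build_cell_features(sim$sweeps, cell_id = paste0("c", i))
    list(feat = feat, truth = sim$truth)
  })
  thr_err <- vapply(res, function(r) r$feat$threshold_v - r$truth$threshold_v,
                    numeric(1))
  hw_err <- vapply(res, function(r) r$feat$hw_at_max - r$truth$half_width,
                   numeric(1))
  ad_err <- vapply(res, function(r) {
    r$feat$adaptation_ratio - r$truth$adaptation_ratio
  }, numeric(1))
  cv_err <- vapply(res, function(r) r$feat$cv_isi - r$truth$cv_isi, numeric(1))
  rin_rel <- vapply(res, function(r) {
    r$feat$input_resistance / r$truth$r_in - 1
  }, numeric(1))
  ff_err <- vapply(res, function(r) r$feat$ff_max - r$truth$ff_max, numeric(1))
  expect_lt(max(abs(thr_err)), 1)
  expect_lt(max(abs(hw_err)), 2 * 1000 / 20000)
  expect_lt(max(abs(ad_err)), 0.05)
  expect_lt(max(abs(cv_err)), 2)
  expect_lt(max(abs(rin_rel)), 0.02)
  expect_equal(max(abs(ff_err)), 0)
})

test_that("features are invariant to a constant voltage offset", {
  sim <- make_cell(79)
  f1 <- build_cell_features(sim$sweeps)
  shifted <- lapply(sim$sweeps, function(sw) {
    new_sweep(sw$t, sw$v + 10, sw$i_cmd, attr(sw, "fs"),
              attr(sw, "step_onset"), attr(sw, "step_offset"))
  })
  f2 <- build_cell_features(shifted)
  expect_equal(f2$v_rest - f1$v_rest, 10, tolerance = 1e-9)
  expect_equal(f2$threshold_v - f1$threshold_v, 10, tolerance = 1e-9)
  expect_equal(f2$amp_at_max, f1$amp_at_max, tolerance = 1e-9)
  expect_equal(f2$hw_at_max, f1$hw_at_max, tolerance = 1e-9)
  expect_equal(f2$adaptation_ratio, f1$adaptation_ratio, tolerance = 1e-12)
})

test_that("an all-subthreshold cell flags its spike-dependent fields undefined", {
  sim <- simulate_current_clamp(
    cell_sim_params(n_steps = 6, step_start = -300, step_size = 50, seed = 80),
    n_repeats = 0
  )
  stopifnot(all(sim$truth$spike_counts == 0))
  feat <- build_cell_features(sim$sweeps)
  expect_true(is.na(feat$threshold_v))
  expect_true(is.na(feat$ff_max))
  expect_true(is.na(feat$adaptation_ratio))
  expect_false(is.na(feat$v_rest))
  expect_false(is.na(feat$input_resistance))
  expect_equal(feat$persistent_firing, "indeterminate")
})

test_that("feature extraction is deterministic for fixed input", {
  sim <- make_cell(81)
  f1 <- build_cell_features(sim$sweeps)
  f2 <- build_cell_features(sim$sweeps)
  expect_identical(f1, f2)
})
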