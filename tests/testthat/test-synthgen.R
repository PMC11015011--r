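test_that("stimulus schedules honor duration, repetitions, ISI bounds and determinism", {
  sch <- generate_stimulus_schedule(300, seed = 11)
  tr <- sch$trials
  expect_gte(nrow(tr), 48)
  reps <- table(factor(tr$direction_deg, levels = seq(0, 315, by = 45)))
  expect_true(all(reps >= 6))
  expect_lte(max(reps) - min(reps), 1)          # balanced block draws
  # sorted, non-overlapping, ISIs within [1, 5] s (whole-frame rounding)
  expect_true(all(diff(tr$onset_frame) > 0))
  gaps <- (tr$onset_frame[-1] - (tr$onset_frame[-nrow(tr)] +
                                   tr$duration_frames[-nrow(tr)])) * sch$frame_period_s
  expect_true(all(gaps >= 1 - 0.08 & gaps <= 5 + 0.08))
  expect_identical(generate_stimulus_schedule(300, seed = 11)$trials, tr)
  expect_false(identical(generate_stimulus_schedule(300, seed = 12)$trials, tr))
})

test_that("zero-repetition and infeasible schedules are handled explicitly", {
  empty <- generate_stimulus_schedule(1, reps_min = 0, frame_period_s = 0.08)
  expect_identical(nrow(empty$trials), 0L)
  expect_identical(empty$session_frames, as.integer(round(1 / 0.08)))
  expect_error(generate_stimulus_schedule(30, reps_min = 6),
               "infeasible")
})

test_that("population membership follows configured fractions, overlap and exclusivity", {
  cfg <- synth_config(n_neurons = 100, n_ensembles = 1, frac_on = 0.2, frac_off = 0.26)
  gt <- generate_population(cfg, seed = 1)
  counts <- table(gt$membership[, 1])[c("on", "off", "non")]
  expect_identical(as.integer(counts), c(20L, 26L, 54L))
  # zero-onsemble configuration
  gt0 <- generate_population(synth_config(n_neurons = 50, n_ensembles = 2,
                                          frac_on = 0), seed = 1)
  expect_false(any(gt0$membership == "on"))
  # full overlap across two ensembles duplicates membership
  gt1 <- generate_population(synth_config(n_neurons = 100, n_ensembles = 2,
                                          overlap = 1), seed = 2)
  expect_identical(gt1$membership[, 1], unname(gt1$membership[, 2]))
  expect_error(synth_config(frac_on = 0.6, frac_off = 0.6), "sum")
})

test_that("raster rates follow the planted condition structure", {
  cfg <- synth_config(n_neurons = 60, frac_non_pref = 0, frac_unspecific = 0,
                      frac_interstim = 0)
  sch <- generate_stimulus_schedule(300, seed = 3)
  gt <- generate_population(cfg, seed = 3)

  # total suppression: offsemble members never spike in their suppressing trials
  ra0 <- simulate_raster(gt, sch, rates = list(suppression = 0), seed = 3)
  for (e in 1:4) {
    off <- which(gt$membership[, e] == "off")
    sig <- truth_signal(gt, sch, e)
    expect_identical(sum(ra0$spikes[off, sig == 1]), 0L)
  }

  # gain 1 / suppression 1: everything statistically at baseline (3 binomial SE)
  ra1 <- simulate_raster(gt, sch, rates = list(baseline = 0.05, gain = 1,
                                               suppression = 1), seed = 4)
  rate <- mean(ra1$spikes)
  se <- sqrt(0.05 * 0.95 / length(ra1$spikes))
  expect_lt(abs(rate - 0.05), 3 * se)

  # evoked mean matches baseline x gain within a binomial CI
  ra2 <- simulate_raster(gt, sch, rates = list(baseline = 0.05, gain = 10),
                         seed = 5)
  on1 <- which(gt$membership[, 1] == "on")
  sig1 <- truth_signal(gt, sch, 1)
  p_hat <- mean(ra2$spikes[on1, sig1 == 1])
  n_obs <- length(on1) * sum(sig1)
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / n_obs))

  # invalid probability after gain
  expect_error(simulate_raster(gt, sch, rates = list(baseline = 0.2, gain = 10),
                               seed = 1), "outside")
  # determinism
  expect_identical(simulate_raster(gt, sch, seed = 9)$spikes,
                   simulate_raster(gt, sch, seed = 9)$spikes)
})

test_that("calcium synthesis produces exponential transients with the planted kinetics", {
  cfg <- synth_config(n_neurons = 1, n_ensembles = 1, frac_on = 0, frac_off = 0,
                      frac_non_pref = 0, frac_unspecific = 0, frac_interstim = 0)
  sch <- generate_stimulus_schedule(60, reps_min = 0, seed = 1)
  gt <- generate_population(cfg, seed = 1)
  spikes <- matrix(0L, 1, sch$session_frames)
  spikes[1, 100] <- 1L
  ra <- structure(list(spikes = spikes, frame_period_s = 0.08),
                  class = "spike_raster")
  tr <- synthesize_calcium(ra, gt, schedule = NULL, neuropil_level = 0,
                           noise_sd = 0, drift_amp = 0, seed = 1)
  # round-trip decay fit recovers the planted 5.8 s within 2%
  fit <- fit_decay(tr$F_roi[1, ], c(100, 100 + 60), frame_period_s = 0.08)
  expect_lt(abs(fit$tau_s - 5.8) / 5.8, 0.02)
  expect_lt(abs(fit$a - 0.3) / 0.3, 0.02)

  # zero spikes, zero noise: flat at the neuropil baseline
  ra0 <- ra; ra0$spikes[] <- 0L
  tr0 <- synthesize_calcium(ra0, gt, neuropil_level = 1, noise_sd = 0,
                            drift_amp = 0, seed = 1)
  expect_equal(tr0$F_roi, tr0$F_neuropil, tolerance = 1e-12)

  # seed changes noise, not transient timing
  trA <- synthesize_calcium(ra, gt, noise_sd = 0.05, seed = 1)
  trB <- synthesize_calcium(ra, gt, noise_sd = 0.05, seed = 2)
  expect_false(identical(trA$F_roi, trB$F_roi))
  # the underlying transient is seed-independent: noiseless syntheses agree
  trC <- synthesize_calcium(ra, gt, noise_sd = 0, drift_amp = 0,
                            neuropil_level = 0, seed = 3)
  trD <- synthesize_calcium(ra, gt, noise_sd = 0, drift_amp = 0,
                            neuropil_level = 0, seed = 4)
  expect_identical(trC$F_roi, trD$F_roi)
})

test_that("behavior traces have block-structured running at the target occupancy", {
  b0 <- simulate_behavior(5000, run_fraction = 0, seed = 1)
  expect_true(all(b0$speed_cm_s < 1))
  b <- simulate_behavior(10000, run_fraction = 0.5, seed = 2)
  running <- mean(b$speed_cm_s > 1)
  expect_gte(running, 0.45); expect_lte(running, 0.55)
  expect_identical(simulate_behavior(1000, run_fraction = 0.3, seed = 5)$speed_cm_s,
                   simulate_behavior(1000, run_fraction = 0.3, seed = 5)$speed_cm_s)
  # bout structure: running frames come in runs, not isolated frames
  runs <- rle(b$speed_cm_s > 1)
  expect_gt(mean(runs$lengths[runs$values]), 5)
})
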