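test_that("neuropil normalization matches its closed form and guards division", {
  expect_equal(neuropil_correct(rep(2, 5), rep(1, 5)), rep(1, 5))
  expect_equal(neuropil_correct(1:5, 1:5), rep(0, 5))
  expect_equal(neuropil_correct(c(3, 1), c(2, 2)), c(0.5, -0.5))
  expect_error(neuropil_correct(c(1, 1), c(1, 1e-9)), "ROI")
})

test_that("PSNR follows 20 log10(peak/std) with its degenerate conventions", {
  fn <- rnorm(500)
  s <- sd(fn)
  expect_equal(compute_psnr(fn + c(s, rep(0, 499)), fn), 0)
  expect_equal(compute_psnr(fn + c(10 * s, rep(0, 499)), fn), 20)
  expect_equal(compute_psnr(fn + c(10^0.5 * s, rep(0, 499)), fn), 10,
               tolerance = 1e-10)
  expect_identical(compute_psnr(fn - abs(fn) - 1, fn), -Inf)
  expect_error(compute_psnr(1:5, rep(1, 5)), "variance")
})

test_that("ROI selection is strict at the cutoff and monotone in it", {
  # three ROIs engineered to PSNR ~5, 10, 15 dB
  set.seed(7)
  fn <- 1 + rnorm(1000, sd = 0.1)
  mk <- function(db) fn + c(10^(db / 20) * sd(fn), rep(0, 999))
  ts <- structure(list(F_roi = rbind(mk(5), mk(10), mk(15)),
                       F_neuropil = rbind(fn, fn, fn),
                       frame_period_s = 0.08), class = "trace_set")
  sel <- select_rois(ts, psnr_min = 10)
  expect_identical(sum(sel$qc$passed), 1L)           # strictly > 10 dB
  expect_equal(sel$qc$threshold,
               pmax(0.04 - 0.002 * sel$qc$psnr_db, 0.01))
  sel_all <- select_rois(ts, psnr_min = -Inf)
  expect_identical(sum(sel_all$qc$passed), 3L)
  counts <- vapply(c(-Inf, 0, 5, 10), function(m)
    sum(select_rois(ts, psnr_min = m)$qc$passed), integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(select_rois(ts, psnr_min = 100), "no ROI")
})

test_that("median/min/max smoothing removes brief events and keeps plateaus", {
  expect_equal(smooth_trace(rep(3, 50), 0.24, 0.08), rep(3, 50))
  spike <- rep(0, 50); spike[25] <- 5
  expect_equal(smooth_trace(spike, 0.24, 0.08), rep(0, 50))
  plateau <- rep(0, 60); plateau[20:40] <- 1
  expect_equal(smooth_trace(plateau, 0.24, 0.08), plateau)
  # offset equivariance of the whole chain
  x <- abs(rnorm(80))
  expect_equal(smooth_trace(x + 2, 0.5, 0.08), smooth_trace(x, 0.5, 0.08) + 2)
  expect_error(smooth_trace(x, 0.01, 0.08), "window")
})

test_that("AR(1) deconvolution recovers isolated events and stays nonnegative", {
  gamma <- 0.95
  y <- rep(0, 120); y[30:120] <- gamma^(0:90)
  s <- infer_spikes(y, gamma, lam = 0, baseline_correct = FALSE)
  expect_equal(which(s > 1e-6), 30L)
  expect_equal(s[30], 1, tolerance = 1e-8)
  expect_equal(infer_spikes(rep(0, 50), 0.9, lam = 0, baseline_correct = FALSE),
               rep(0, 50))
  set.seed(1)
  for (i in 1:5) expect_true(all(infer_spikes(rnorm(200), 0.9) >= 0))
  expect_error(infer_spikes(y, 1.2), "gamma")
})

test_that("binarization applies the PSNR-proportional threshold with its floor", {
  expect_identical(binarize_spikes(c(0.01, 0.03), 10), c(0L, 1L))
  # raw threshold at 20 dB is zero; the floor takes over
  expect_identical(binarize_spikes(c(0.005, 0.02), 20), c(0L, 1L))
  expect_identical(binarize_spikes(rep(0, 10), 12), rep(0L, 10))
  expect_error(binarize_spikes(1, Inf), "finite")
})

test_that("raster assembly stacks rows, keeps counts, and rejects bad input", {
  rows <- replicate(3, rbinom(100, 1, 0.1), simplify = FALSE)
  ra <- build_raster(rows, 0.08)
  expect_identical(dim(ra$spikes), c(3L, 100L))
  expect_identical(rowSums(ra$spikes), vapply(rows, sum, numeric(1)))
  expect_error(build_raster(list(), 0.08), "zero ROIs")
  expect_error(build_raster(list(1:3 * 0, rep(0, 5)), 0.08), "ragged")
})

test_that("decay fitting is exact on noiseless exponentials and flags degeneracy", {
  tt <- (0:49) * 0.08
  y <- 1 * exp(-tt / 2.5)
  fit <- fit_decay(y, c(1, 50), 0.08)
  expect_equal(fit$a, 1, tolerance = 1e-6)
  expect_equal(fit$tau_s, 2.5, tolerance = 1e-6)
  expect_false(fit$at_bound)
  # oracle equivalence: log-linear closed form on noiseless data
  ll <- lm(log(y) ~ tt)
  expect_equal(fit$tau_s, -1 / unname(coef(ll)[2]), tolerance = 1e-6)
  expect_equal(fit$a, exp(unname(coef(ll)[1])), tolerance = 1e-6)
  # constant trace pushes tau to the upper bound and is flagged
  cfit <- fit_decay(rep(1, 30), c(1, 30), 0.08, tau_bounds = c(0.05, 60))
  expect_true(cfit$at_bound)
  expect_error(fit_decay(y, c(1, 2), 0.08), "3 samples")
})

test_that("decay recovery bias stays below 5% at SNR 10", {
  set.seed(42)
  tt <- (0:49) * 0.08
  taus <- replicate(500, {
    y <- exp(-tt / 2.5) + rnorm(50, sd = 0.1)
    fit_decay(pmax(y, 1e-6), c(1, 50), 0.08)$tau_s
  })
  expect_lt(abs(mean(taus) - 2.5) / 2.5, 0.05)
})

test_that("decay constants separate by stimulation condition on planted kinetics", {
  sess <- planted_session(7, regime = "paper", n_neurons = 60)
  tr <- synthesize_calcium(sess$ra, sess$gt, sess$sch, noise_sd = 0.01, seed = 7)
  ff <- neuropil_correct(tr$F_roi, tr$F_neuropil)
  sm <- t(apply(ff, 1, smooth_trace, window_s = 0.5, frame_period_s = 0.08))
  dc <- decay_by_condition(sm, sess$sch, sess$gt$membership,
                           sess$gt$ensemble_orientations_deg)
  expect_gt(dc$condition_means["pre_onset"] / dc$condition_means["during"], 2)
  expect_lt(dc$condition_means["during"], dc$condition_means["pre_onset"])

  # no stimulus: only the spontaneous condition is populated
  sch0 <- generate_stimulus_schedule(60, reps_min = 0, seed = 1)
  dc0 <- decay_by_condition(sm[, 1:sch0$session_frames, drop = FALSE], sch0,
                            sess$gt$membership,
                            sess$gt$ensemble_orientations_deg)
  expect_true(all(dc0$fits$condition == "spontaneous"))
  expect_true(is.na(dc0$condition_means["during"]))
})

test_that("the preprocessing chain recovers sparse planted spikes from clean traces", {
  reg <- synth_regime("clean", n_neurons = 20)
  sch <- generate_stimulus_schedule(300, reps_min = 0, seed = 3)
  gt <- generate_population(reg$config, seed = 3)
  ra <- simulate_raster(gt, sch, rates = list(baseline = 0.002, gain = 1,
                                              suppression = 1), seed = 3)
  tr <- synthesize_calcium(ra, gt, sch, noise_sd = 0, seed = 3)
  pre <- preprocess_traces(tr)
  keep <- which(pre$qc$passed)
  jacc <- vapply(seq_along(keep), function(i) {
    jaccard_similarity(pre$raster$spikes[i, ], ra$spikes[keep[i], ])
  }, numeric(1))
  expect_gte(mean(jacc), 0.9)
  expect_gte(median(jacc), 0.9)
})
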