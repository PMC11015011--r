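make_part_table <- function(classes) {
  data.frame(neuron_id = seq_along(classes), class = classes)
}

test_that("group activity counts members and the combined ensemble criterion", {
  X <- matrix(0L, 6, 3)
  X[1:2, 1] <- 1L                     # both onsemble members active in frame 1
  X[3:4, 2] <- 1L                     # both offsemble members active in frame 2
  X[c(1, 3), 3] <- 1L                 # one of each in frame 3
  part <- make_part_table(c("onsemble", "onsemble", "offsemble", "offsemble",
                            "nonparticipant", "nonparticipant"))
  on <- group_activity(X, part, "onsemble")
  expect_equal(on$series, c(1, 0, 0.5))
  # ensemble criterion: active onsemble + inactive offsemble over members
  dag <- group_activity(X, part, "ensemble_dagger")
  expect_equal(dag$series[1], 1)      # all on active, all off silent
  expect_equal(dag$series[2], 0)      # all on silent, all off active
  expect_equal(dag$series[3], 0.5)
  expect_error(group_activity(X, make_part_table(rep("nonparticipant", 6)),
                              "onsemble"), "empty")
  nt <- group_activity(X, part, "nonparticipant_tuned", tuned_ids = 5L)
  expect_identical(nt$members, 5L)
})

test_that("trial responses average the stimulus window only", {
  sch <- structure(list(trials = data.frame(onset_frame = c(10L, 50L),
                                            duration_frames = 10L,
                                            direction_deg = c(0, 90)),
                        frame_period_s = 0.08, session_frames = 100L),
                   class = "stimulus_schedule")
  act <- rep(0, 100)
  act[11:15] <- 1                     # half the first trial's frames
  act[90:100] <- 1                    # outside any trial
  tr <- trial_responses(act, sch)
  expect_equal(tr$response, c(0.5, 0))
  expect_equal(trial_responses(rep(0, 100), sch)$response, c(0, 0))
  bad <- sch; bad$trials$onset_frame[2] <- 95L
  expect_error(trial_responses(act, bad), "past the end")
})

test_that("orientation selectivity follows the doubled-angle resultant", {
  mk <- function(R) {
    data.frame(orientation_deg = rep(c(0, 45, 90, 135), each = 3),
               response = rep(R, each = 3))
  }
  one <- orientation_selectivity(mk(c(1, 0, 0, 0)))
  expect_equal(one$osi, 1); expect_equal(one$theta_pref_deg, 0)
  expect_equal(orientation_selectivity(mk(c(0.4, 0.4, 0.4, 0.4)))$osi, 0)
  hand <- orientation_selectivity(mk(c(1, 0.5, 0, 0.5)))
  expect_equal(hand$osi, 0.5); expect_equal(hand$theta_pref_deg, 0)
  # scale invariance and rotation equivariance
  expect_equal(orientation_selectivity(mk(3 * c(1, 0.5, 0, 0.5)))$osi, 0.5)
  rot <- orientation_selectivity(mk(c(0.5, 1, 0.5, 0)))
  expect_equal(rot$theta_pref_deg, 45)
  expect_true(is.na(orientation_selectivity(mk(c(0, 0, 0, 0)))$osi))
})

test_that("the Hotelling test detects tuning and never exceeds its nominal size", {
  set.seed(12)
  tuned <- data.frame(orientation_deg = rep(c(0, 45, 90, 135), each = 12),
                      response = c(rnorm(12, 0.8, 0.05), rnorm(36, 0.05, 0.03)))
  tuned$response <- pmax(tuned$response, 0)
  expect_lt(hotelling_test(tuned)$p, 0.01)

  # under a balanced stimulus design the raw second moment of the
  # doubled-angle vectors overstates the variability of their mean, so the
  # test is conservative: the false-positive rate stays at or below alpha
  rejections <- vapply(1:300, function(b) {
    set.seed(1000 + b)
    null <- data.frame(orientation_deg = rep(c(0, 45, 90, 135), each = 6),
                       response = runif(24, 0, 1))
    hotelling_test(null)$p < 0.05
  }, logical(1))
  expect_lte(mean(rejections), 0.05 + 2 * sqrt(0.05 * 0.95 / 300))

  zero <- data.frame(orientation_deg = rep(c(0, 45, 90, 135), 3), response = 0)
  res <- hotelling_test(zero)
  expect_true(res$flagged); expect_equal(res$p, 1)
  expect_error(hotelling_test(tuned[1:2, ]), ">= 3")
})

test_that("the bounded Gaussian fit recovers parameters and matches grid search", {
  wrap <- function(d) ((d + 90) %% 180) - 90
  theta <- c(0, 45, 90, 135)
  y <- 0.8 * exp(-wrap(theta - 90)^2 / (2 * 20^2))
  names(y) <- theta
  fit <- fit_tuning_curve(y)
  expect_equal(fit$a, 0.8, tolerance = 1e-4)
  expect_equal(fit$theta_pref_deg, 90, tolerance = 1e-3)
  expect_equal(fit$sigma_deg, 20, tolerance = 1e-3)
  # the model reproduces the peak exactly at theta_pref
  expect_equal(fit$a * exp(0), fit$a)
  # oracle: no better RSS on a 1-degree grid
  set.seed(13)
  for (rep in 1:5) {
    yy <- runif(4); names(yy) <- theta
    expect_lte(fit_tuning_curve(yy)$rss, grid_tuning_rss(yy) + 1e-6)
  }
  flat <- setNames(rep(0.4, 4), theta)
  ffit <- fit_tuning_curve(flat)
  expect_true(ffit$at_bound)
  expect_equal(ffit$sigma_deg, 90, tolerance = 1e-6)
  expect_error(fit_tuning_curve(flat[1:3]), ">= 4")
})

test_that("activation probability and evoked duration read the trial structure", {
  dur <- 25L
  onsets <- seq(20L, 900L, by = 80L)
  sch <- structure(list(trials = data.frame(onset_frame = onsets,
                                            duration_frames = dur,
                                            direction_deg = rep(c(0, 90),
                                                                length.out = length(onsets))),
                        frame_period_s = 0.08, session_frames = 1000L),
                   class = "stimulus_schedule")
  act <- rep(0, 1000)
  for (o in onsets[seq(1, length(onsets), by = 2)]) act[o + 5] <- 1  # frame 5 of 0-deg trials
  ap <- activation_probability(act, sch, theta_pref = 0)
  expect_equal(ap$max, 1)
  expect_equal(ap$latency_s, 4 * 0.08)
  expect_equal(activation_probability(rep(0, 1000), sch, 0)$max, 0)
  # 6 of 12 trials active at the peak frame
  act2 <- rep(0, 1000)
  zero_trials <- onsets[seq(1, length(onsets), by = 2)]
  for (o in zero_trials[seq(1, length(zero_trials), by = 2)]) act2[o + 3] <- 1
  ap2 <- activation_probability(act2, sch, 0)
  expect_equal(ap2$max, sum(seq_along(zero_trials) %% 2 == 1) / length(zero_trials))
  expect_error(activation_probability(act, sch, 30), "no trials")

  # durations
  full <- rep(0, 1000)
  for (o in zero_trials) full[(o + 1):(o + dur)] <- 1
  expect_equal(evoked_duration(full, sch, 0), dur * 0.08)
  expect_equal(evoked_duration(rep(0, 1000), sch, 0), 0)
  ten <- rep(0, 1000)
  for (o in zero_trials) ten[(o + 1):(o + 10)] <- 1
  sch81 <- sch; sch81$frame_period_s <- 0.081
  expect_equal(evoked_duration(ten, sch81, 0), 10 * 0.081)
})

test_that("single-cell tuning classes separate tuned, interstim and untuned neurons", {
  sch <- generate_stimulus_schedule(300, seed = 14)
  F_ <- sch$session_frames
  stim0 <- truth_signal(list(ensemble_orientations_deg = 0), sch, 1)
  in_any <- rep(0L, F_)
  for (t in seq_len(nrow(sch$trials))) {
    in_any[(sch$trials$onset_frame[t] + 1):(sch$trials$onset_frame[t] +
                                              sch$trials$duration_frames[t])] <- 1L
  }
  set.seed(15)
  hits <- vapply(1:20, function(b) {
    sp <- rbinom(F_, 1, ifelse(stim0 == 1, 0.3, 0.02))
    cl <- classify_cell_tuning(sp, sch)
    wrap <- function(d) ((d + 90) %% 180) - 90
    cl$class == "tuned" && abs(wrap(cl$theta_pref_deg - 0)) < 22.5
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  sp_inter <- rbinom(F_, 1, ifelse(in_any == 1, 0.001, 0.1))
  expect_identical(classify_cell_tuning(sp_inter, sch)$class, "interstim")
  sp_unsp <- rbinom(F_, 1, ifelse(in_any == 1, 0.15, 0.02))
  expect_identical(classify_cell_tuning(sp_unsp, sch)$class, "unspecific")

  untuned_rate <- mean(vapply(1:200, function(b) {
    set.seed(2000 + b)
    classify_cell_tuning(rbinom(F_, 1, 0.05), sch)$class == "untuned"
  }, logical(1)))
  expect_gt(untuned_rate, 0.85)
})

test_that("ensemble composition counts members by tuning class and conserves totals", {
  part <- rbind(
    data.frame(neuron_id = 1:6, ensemble_id = 1,
               class = c("onsemble", "onsemble", "offsemble", "nonparticipant",
                         "nonparticipant", "nonparticipant"), epi = 0.5),
    data.frame(neuron_id = 1:6, ensemble_id = 2,
               class = c("onsemble", "nonparticipant", "offsemble", "offsemble",
                         "nonparticipant", "nonparticipant"), epi = 0.5))
  cells <- data.frame(class = c("tuned", "tuned", "tuned", "unspecific",
                                "interstim", "untuned"),
                      theta_pref_deg = c(0, 90, 0, NA, NA, NA))
  comp <- ensemble_composition(part, cells, c(`1` = 0, `2` = 90))
  e1on <- comp$composition[comp$composition$ensemble_id == 1 &
                             comp$composition$group == "onsemble", ]
  expect_identical(e1on$pref, 1L)      # neuron 1 tuned to the ensemble's 0 deg
  expect_identical(e1on$nonpref, 1L)   # neuron 2 tuned to 90 deg
  sums <- rowSums(comp$composition[, c("pref", "nonpref", "unspecific",
                                       "interstim", "untuned")])
  sizes <- vapply(seq_len(nrow(comp$composition)), function(i) {
    sum(part$ensemble_id == comp$composition$ensemble_id[i] &
          part$class == comp$composition$group[i])
  }, numeric(1))
  expect_equal(unname(sums), sizes)
  expect_identical(comp$shared$onsemble, 1L)   # neuron 1 in both onsembles
})
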