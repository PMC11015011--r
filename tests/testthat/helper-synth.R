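# Shared fixture builders and independent oracles. Everything is generated
# in code at test time; no stored data.

# 100-frame session with an ensemble occupying frames 1..50 and one neuron
# whose spikes are placed by `spike_frames`
epi_case <- function(spike_frames) {
  signal <- c(rep(1L, 50), rep(0L, 50))
  spikes <- rep(0L, 100)
  spikes[spike_frames] <- 1L
  list(spikes = spikes, signal = signal)
}

# planted-session bundle under a named regime
planted_session <- function(seed, regime = "clean", n_neurons = 200,
                            duration_s = 300, reps_min = 6) {
  reg <- synth_regime(regime, n_neurons = n_neurons)
  sch <- generate_stimulus_schedule(duration_s, reps_min = reps_min, seed = seed)
  gt <- generate_population(reg$config, seed = seed)
  ra <- simulate_raster(gt, sch, rates = reg$rates, seed = seed)
  list(sch = sch, gt = gt, ra = ra, rates = reg$rates)
}

# planted occurrence signal of ensemble e: frames of its orientation's trials
truth_signal <- function(gt, sch, e) {
  o <- gt$ensemble_orientations_deg[e]
  sig <- rep(0L, sch$session_frames)
  tr <- sch$trials
  for (t in which(tr$direction_deg %% 180 == o)) {
    sig[(tr$onset_frame[t] + 1):(tr$onset_frame[t] + tr$duration_frames[t])] <- 1L
  }
  sig
}

# planted frame labels: 1..4 by trial orientation, 0 between trials
truth_frame_labels <- function(sch) {
  lab <- rep(0L, sch$session_frames)
  tr <- sch$trials
  for (t in seq_len(nrow(tr))) {
    o <- tr$direction_deg[t] %% 180
    lab[(tr$onset_frame[t] + 1):(tr$onset_frame[t] + tr$duration_frames[t])] <-
      1L + as.integer(o / 45)
  }
  lab
}

f1_score <- function(pred, truth, positive) {
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  if (2 * tp + fp + fn == 0) return(NA_real_)
  2 * tp / (2 * tp + fp + fn)
}

# exhaustive informedness scan, independent of optimal_threshold()
brute_informedness <- function(responses, positive) {
  best <- -Inf
  for (dir in c(">=", "<=")) {
    for (c0 in unique(responses)) {
      fires <- if (dir == ">=") responses >= c0 else responses <= c0
      J <- mean(fires[positive]) - mean(fires[!positive])
      if (J > best) best <- J
    }
  }
  best
}

# 1-degree grid-search Gaussian tuning fit (closed-form amplitude)
grid_tuning_rss <- function(orientation_means) {
  theta <- as.numeric(names(orientation_means))
  y <- as.numeric(orientation_means)
  wrap <- function(d) ((d + 90) %% 180) - 90
  best <- Inf
  for (tp in 0:179) {
    for (sg in seq(1, 90, by = 1)) {
      g <- exp(-wrap(theta - tp)^2 / (2 * sg^2))
      a <- min(max(sum(y * g) / sum(g^2), 0), 1)
      rss <- sum((y - a * g)^2)
      if (rss < best) best <- rss
    }
  }
  best
}

# analysis used by the selectivity/decoding ordering checks: per stimulus
# orientation pick the best-matching significant ensemble (the "four
# necessary ensembles"), then tuning of ensembles, member groups, tuned
# single neurons, and decoding accuracies
ordering_analysis <- function(sess, seed) {
  fit <- detect_ensembles(sess$ra, seed = seed)
  etab <- ensemble_tuning(fit, sess$sch)
  part <- participation_all(fit, sess$ra)
  sig <- etab[etab$significant, , drop = FALSE]
  orients <- c(0, 45, 90, 135)
  wrap <- function(d) ((d + 90) %% 180) - 90
  best_e <- vapply(orients, function(o) {
    mi <- which(abs(wrap(sig$theta_pref_deg - o)) < 22.5)
    if (!length(mi)) return(NA_integer_)
    as.integer(sig$ensemble_id[mi[which.max(sig$osi[mi])]])
  }, integer(1))

  cells <- lapply(seq_len(nrow(sess$ra$spikes)), function(i) {
    classify_cell_tuning(sess$ra$spikes[i, ], sess$sch)
  })
  cell_class <- vapply(cells, `[[`, character(1), "class")
  cell_theta <- vapply(cells, `[[`, numeric(1), "theta_pref_deg")
  tuned_ids <- which(cell_class == "tuned")

  groups <- list(ensemble = list(), neurons = list(), onsemble = list(),
                 offsemble = list(), nonpart = list())
  osi <- sigma <- lapply(groups, function(x) numeric(0))
  for (e in best_e[!is.na(best_e)]) {
    row <- which(fit$ensemble_ids == e)
    p1 <- part[part$ensemble_id == e, ]
    units <- list(
      ensemble = fit$signals[row, ],
      onsemble = tryCatch(group_activity(sess$ra, p1, "onsemble")$series,
                          error = function(e) NULL),
      offsemble = tryCatch(group_activity(sess$ra, p1, "offsemble")$series,
                           error = function(e) NULL),
      nonpart = tryCatch(group_activity(sess$ra, p1, "nonparticipant_tuned",
                                        tuned_ids = tuned_ids)$series,
                         error = function(e) NULL))
    for (g in names(units)) {
      if (is.null(units[[g]])) next
      tu <- unit_tuning(trial_responses(units[[g]], sess$sch))
      osi[[g]] <- c(osi[[g]], tu$osi)
      sigma[[g]] <- c(sigma[[g]], tu$curve$sigma_deg)
    }
  }
  for (i in tuned_ids) {
    tu <- unit_tuning(trial_responses(sess$ra$spikes[i, ], sess$sch))
    osi$neurons <- c(osi$neurons, tu$osi)
    sigma$neurons <- c(sigma$neurons, tu$curve$sigma_deg)
  }

  true_or <- sess$sch$trials$direction_deg %% 180
  acc_ens <- NA_real_
  if (!any(is.na(best_e))) {
    rm_ <- t(vapply(seq_along(orients), function(i) {
      row <- which(fit$ensemble_ids == best_e[i])
      trial_responses(fit$signals[row, ], sess$sch)$response
    }, numeric(nrow(sess$sch$trials))))
    rownames(rm_) <- orients
    acc_ens <- decode_orientations(rm_, true_or, seed = seed)$accuracy
  }
  resp_m <- t(vapply(seq_len(nrow(sess$ra$spikes)), function(i) {
    trial_responses(sess$ra$spikes[i, ], sess$sch)$response
  }, numeric(nrow(sess$sch$trials))))
  tn <- data.frame(neuron_id = tuned_ids, theta_pref_deg = cell_theta[tuned_ids])
  acc_sets <- tryCatch(
    neuron_set_confusions(tn, resp_m, true_or, seed = seed)$accuracy,
    error = function(e) NA_real_)

  list(fit = fit, part = part, osi = lapply(osi, mean),
       sigma = lapply(sigma, mean),
       acc_ensemble = acc_ens, acc_neuron_sets = acc_sets,
       best_e = best_e)
}
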