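#' Synthetic recording generator
#'
#' Generates the study conditions the pipeline is designed for: randomized
#' drifting-grating schedules, orientation-tuned population spiking with
#' planted coactivated (onsemble) and suppressed (offsemble) member sets,
#' GCaMP6s-like calcium traces with neuropil contamination, and
#' block-structured locomotion, so that every downstream stage can be tested
#' without external recordings.
#'
#' @name synthgen
NULL

#' Generate a randomized drifting-grating stimulus schedule
#'
#' Directions are drawn in balanced shuffled blocks (each block one
#' presentation of every direction), stimuli last \code{stim_dur_s} seconds
#' and are separated by inter-stimulus intervals drawn uniformly from
#' \code{[isi_min_s, isi_max_s]}, rounded to whole frames. The session starts
#' with an inter-stimulus (blank) period.
#'
#' @param duration_s session duration in seconds.
#' @param directions_deg grating drift directions in degrees
#'   (default the 8 cardinal/oblique directions at 45 degree steps).
#' @param reps_min minimum number of presentations of each direction.
#' @param stim_dur_s stimulus duration in seconds (default 2).
#' @param isi_min_s,isi_max_s inter-stimulus interval bounds in seconds.
#' @param frame_period_s imaging frame period in seconds (default 0.08,
#'   the effective volumetric rate of 3-plane imaging).
#' @param seed integer seed; the schedule is deterministic given the seed.
#' @return an object of class \code{"stimulus_schedule"}: a list with
#'   \code{trials} (data.frame with \code{onset_frame} (0-based),
#'   \code{duration_frames}, \code{direction_deg}), \code{frame_period_s}
#'   and \code{session_frames}.
#' @export
generate_stimulus_schedule <- function(duration_s,
                                       directions_deg = seq(0, 315, by = 45),
                                       reps_min = 6,
                                       stim_dur_s = 2,
                                       isi_min_s = 1,
                                       isi_max_s = 5,
                                       frame_period_s = 0.08,
                                       seed = 1L) {
  if (isi_min_s > isi_max_s) stopf("isi_min_s (%g) exceeds isi_max_s (%g)", isi_min_s, isi_max_s)
  if (frame_period_s <= 0) stopf("frame_period_s must be positive")
  session_frames <- as.integer(round(duration_s / frame_period_s))
  ndir <- length(directions_deg)
  if (reps_min > 0 && duration_s < reps_min * ndir * (stim_dur_s + isi_min_s)) {
    stopf(paste0(
      "infeasible schedule: %g s cannot hold %d repetitions of %d directions ",
      "(need at least %g s)"), duration_s, reps_min, ndir,
      reps_min * ndir * (stim_dur_s + isi_min_s))
  }
  empty <- data.frame(onset_frame = integer(0), duration_frames = integer(0),
                      direction_deg = numeric(0))
  # zero repetitions requested: a stimulus-free (blank) session
  if (reps_min == 0) {
    return(structure(list(trials = empty, frame_period_s = frame_period_s,
                          session_frames = session_frames),
                     class = "stimulus_schedule"))
  }

  dur_frames <- as.integer(round(stim_dur_s / frame_period_s))
  draw_once <- function() {
    onset <- numeric(0); dirs <- numeric(0)
    block <- numeric(0)
    t <- stats::runif(1, isi_min_s, isi_max_s)
    repeat {
      if (t + stim_dur_s > duration_s) break
      if (length(block) == 0) block <- sample(directions_deg)
      onset <- c(onset, t)
      dirs <- c(dirs, block[1]); block <- block[-1]
      t <- t + stim_dur_s + stats::runif(1, isi_min_s, isi_max_s)
    }
    list(onset = onset, dirs = dirs)
  }

  sched <- with_seed(substream_seed(seed, "schedule"), {
    ok <- NULL
    for (attempt in 1:100) {
      cand <- draw_once()
      if (all(table(factor(cand$dirs, levels = directions_deg)) >= reps_min)) {
        ok <- cand; break
      }
    }
    if (is.null(ok)) {
      stopf("infeasible schedule: could not fit %d repetitions of each direction in %g s",
            reps_min, duration_s)
    }
    ok
  })

  if (length(sched$onset) == 0) {
    trials <- empty
  } else {
    trials <- data.frame(
      onset_frame = as.integer(round(sched$onset / frame_period_s)),
      duration_frames = dur_frames,
      direction_deg = sched$dirs
    )
  }
  structure(list(trials = trials, frame_period_s = frame_period_s,
                 session_frames = session_frames),
            class = "stimulus_schedule")
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  cat(sprintf("Stimulus schedule: %d trials over %d frames (%.3f s/frame)\n",
              nrow(x$trials), x$session_frames, x$frame_period_s))
  if (nrow(x$trials)) {
    tab <- table(x$trials$direction_deg)
    cat("  repetitions per direction:",
        paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

#' Configuration for the synthetic population
#'
#' Defaults are the recording conditions the pipeline targets: ~20% onsemble
#' and ~26% offsemble members per ensemble, one ensemble per stimulus
#' orientation, GCaMP6s decay of 5.8 s slowing to 2.5 s under suppression.
#' \code{off_from_on} controls what fraction of each offsemble is drawn from
#' other ensembles' onsemble members (cross-orientation suppression), and
#' \code{overlap} the fraction of membership shared between consecutive
#' ensembles.
#'
#' @param n_neurons number of neurons.
#' @param n_ensembles number of planted ensembles (one per orientation by
#'   default).
#' @param orientations_deg preferred orientation of each ensemble, degrees in
#'   \[0, 180).
#' @param frac_on,frac_off fraction of neurons in each ensemble's onsemble /
#'   offsemble; their sum must not exceed 1.
#' @param overlap fraction of an ensemble's membership copied from the
#'   previous ensemble (1 = identical memberships).
#' @param off_from_on fraction of the remaining offsemble slots drawn from
#'   other ensembles' onsemble members.
#' @param frac_non_pref,frac_unspecific,frac_interstim tuning-class fractions
#'   among neurons that are onsemble members of no ensemble; the remainder is
#'   untuned.
#' @param tau_decay_spont_s,tau_decay_suppressed_s calcium decay constants
#'   (seconds) outside / during a neuron's suppressing stimulus.
#' @param amplitude calcium transient amplitude per spike (dF/F units).
#' @param reliability_on,reliability_non per-trial participation probability
#'   of onsemble members / tuned nonparticipants (1 = respond on every
#'   preferred-orientation trial).
#' @return a validated list of class \code{"synth_config"}.
#' @export
synth_config <- function(n_neurons = 200,
                         n_ensembles = 4,
                         orientations_deg = c(0, 45, 90, 135),
                         frac_on = 0.20,
                         frac_off = 0.26,
                         overlap = 0,
                         off_from_on = 0.7,
                         frac_non_pref = 0.25,
                         frac_unspecific = 0.05,
                         frac_interstim = 0.10,
                         tau_decay_spont_s = 5.8,
                         tau_decay_suppressed_s = 2.5,
                         amplitude = 0.3,
                         reliability_on = 1,
                         reliability_non = 1) {
  if (frac_on + frac_off > 1) {
    stopf("membership fractions sum to %.2f > 1 per ensemble", frac_on + frac_off)
  }
  if (frac_on < 0 || frac_off < 0) stopf("membership fractions must be nonnegative")
  if (overlap < 0 || overlap > 1) stopf("overlap must be in [0, 1]")
  if (off_from_on < 0 || off_from_on > 1) stopf("off_from_on must be in [0, 1]")
  if (frac_non_pref + frac_unspecific + frac_interstim > 1) {
    stopf("nonparticipant tuning-class fractions exceed 1")
  }
  if (tau_decay_spont_s <= 0 || tau_decay_suppressed_s <= 0) stopf("tau values must be > 0")
  if (length(orientations_deg) < n_ensembles) {
    orientations_deg <- rep_len(orientations_deg, n_ensembles)
  }
  structure(list(
    n_neurons = n_neurons, n_ensembles = n_ensembles,
    orientations_deg = orientations_deg[seq_len(n_ensembles)],
    frac_on = frac_on, frac_off = frac_off,
    overlap = overlap, off_from_on = off_from_on,
    frac_non_pref = frac_non_pref, frac_unspecific = frac_unspecific,
    frac_interstim = frac_interstim,
    tau_decay_spont_s = tau_decay_spont_s,
    tau_decay_suppressed_s = tau_decay_suppressed_s,
    amplitude = amplitude,
    reliability_on = reliability_on, reliability_non = reliability_non
  ), class = "synth_config")
}

#' Generate a ground-truth population with planted ensemble structure
#'
#' Assigns every (neuron, ensemble) pair one of the mutually exclusive labels
#' onsemble member ("on"), offsemble member ("off") or nonparticipant
#' ("non"), a tuning class per neuron, per-neuron calcium kinetics, and
#' per-neuron trial reliability. A neuron may hold different labels in
#' different ensembles (e.g. onsemble of one orientation, offsemble of
#' another), which is how cortical cross-orientation suppression enters the
#' synthetic population.
#'
#' @param config a \code{\link{synth_config}}.
#' @param seed integer seed.
#' @return an object of class \code{"synthetic_ground_truth"}: membership
#'   (n_neurons x n_ensembles character matrix in \{"on","off","non"\}),
#'   \code{tuning} data.frame (\code{class} in
#'   \{"pref","unspecific","interstim","untuned"\},
#'   \code{pref_orientation_deg}), \code{kinetics} data.frame,
#'   \code{reliability}, \code{ensemble_orientations_deg}, \code{config},
#'   \code{seed}.
#' @export
generate_population <- function(config = synth_config(), seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  N <- config$n_neurons
  E <- config$n_ensembles
  n_on <- round(config$frac_on * N)
  n_off <- round(config$frac_off * N)

  with_seed(substream_seed(seed, "population"), {
    membership <- matrix("non", N, E,
                         dimnames = list(NULL, paste0("E", seq_len(E))))
    # pass 1: onsembles, chained overlap with the previous ensemble
    for (e in seq_len(E)) {
      if (n_on == 0) next
      if (e == 1) {
        on_e <- sample(N, n_on)
      } else {
        prev_on <- which(membership[, e - 1] == "on")
        n_copy <- min(round(config$overlap * n_on), length(prev_on))
        copied <- if (n_copy > 0) sample(prev_on, n_copy) else integer(0)
        pool <- setdiff(seq_len(N), copied)
        on_e <- c(copied, sample(pool, n_on - n_copy))
      }
      membership[on_e, e] <- "on"
    }
    # pass 2: offsembles; drawn preferentially from other ensembles' onsembles
    for (e in seq_len(E)) {
      if (n_off == 0) next
      taken <- which(membership[, e] == "on")
      off_e <- integer(0)
      if (e > 1 && config$overlap > 0) {
        prev_off <- setdiff(which(membership[, e - 1] == "off"), taken)
        n_copy <- min(round(config$overlap * n_off), length(prev_off))
        if (n_copy > 0) off_e <- sample(prev_off, n_copy)
      }
      other_on <- setdiff(which(apply(membership != "non", 1, any) &
                                  membership[, e] != "on"),
                          c(taken, off_e))
      other_on <- intersect(other_on,
                            which(rowSums(membership == "on") > 0))
      n_from_on <- min(round(config$off_from_on * (n_off - length(off_e))),
                       length(other_on))
      if (n_from_on > 0) off_e <- c(off_e, sample(other_on, n_from_on))
      pool <- setdiff(seq_len(N), c(taken, off_e))
      n_rest <- n_off - length(off_e)
      if (n_rest > length(pool)) stopf("offsemble fraction infeasible for ensemble %d", e)
      if (n_rest > 0) off_e <- c(off_e, sample(pool, n_rest))
      membership[off_e, e] <- "off"
    }

    # tuning: onsemble members are tuned to their (first) ensemble's
    # orientation; the rest split into the configured nonparticipant classes
    tuning <- data.frame(class = rep("untuned", N),
                         pref_orientation_deg = rep(NA_real_, N))
    for (i in seq_len(N)) {
      on_in <- which(membership[i, ] == "on")
      if (length(on_in) > 0) {
        tuning$class[i] <- "pref"
        tuning$pref_orientation_deg[i] <- config$orientations_deg[on_in[1]]
      }
    }
    rest <- which(tuning$class == "untuned")
    n_rest <- length(rest)
    n_pref <- round(config$frac_non_pref * n_rest)
    n_unsp <- round(config$frac_unspecific * n_rest)
    n_inter <- round(config$frac_interstim * n_rest)
    shuffled <- sample(rest)
    pref_idx <- shuffled[seq_len(n_pref)]
    unsp_idx <- shuffled[n_pref + seq_len(n_unsp)]
    inter_idx <- shuffled[n_pref + n_unsp + seq_len(n_inter)]
    tuning$class[pref_idx] <- "pref"
    tuning$pref_orientation_deg[pref_idx] <-
      sample(unique(config$orientations_deg), length(pref_idx), replace = TRUE)
    tuning$class[unsp_idx] <- "unspecific"
    tuning$class[inter_idx] <- "interstim"

    kinetics <- data.frame(
      tau_decay_spont_s = rep(config$tau_decay_spont_s, N),
      tau_decay_suppressed_s = rep(config$tau_decay_suppressed_s, N),
      amplitude = rep(config$amplitude, N)
    )
    reliability <- ifelse(rowSums(membership == "on") > 0,
                          config$reliability_on, config$reliability_non)

    structure(list(
      membership = membership,
      tuning = tuning,
      kinetics = kinetics,
      reliability = reliability,
      ensemble_orientations_deg = config$orientations_deg,
      config = config,
      seed = seed
    ), class = "synthetic_ground_truth")
  })
}

#' @export
print.synthetic_ground_truth <- function(x, ...) {
  cat(sprintf("Synthetic ground truth: %d neurons, %d ensembles\n",
              nrow(x$membership), ncol(x$membership)))
  for (e in seq_len(ncol(x$membership))) {
    cat(sprintf("  %s (%g deg): %d on / %d off / %d non\n",
                colnames(x$membership)[e], x$ensemble_orientations_deg[e],
                sum(x$membership[, e] == "on"), sum(x$membership[, e] == "off"),
                sum(x$membership[, e] == "non")))
  }
  cat("  tuning classes:",
      paste(sprintf("%s:%d", names(table(x$tuning$class)), table(x$tuning$class)),
            collapse = " "), "\n")
  invisible(x)
}

#' Simulate ground-truth spiking as a binary raster
#'
#' Per-frame Bernoulli spiking. During a trial of orientation theta, members
#' of the ensemble planted at theta spike at \code{baseline * gain}
#' (onsemble) or \code{baseline * suppression} (offsemble); tuned
#' nonparticipants matching theta at \code{baseline * gain_nontuned};
#' unspecific neurons are elevated during every trial; interstim neurons are
#' elevated only between trials; everything else stays at baseline.
#' Onsemble members and tuned nonparticipants respond on a given preferred
#' trial with their per-neuron reliability.
#'
#' @param ground_truth a \code{\link{generate_population}} result.
#' @param schedule a \code{\link{generate_stimulus_schedule}} result.
#' @param rates list with elements \code{baseline} (per-frame spike
#'   probability), \code{gain} (evoked multiplier, >= 1), \code{suppression}
#'   (in \[0,1\]), \code{gain_nontuned}, \code{gain_unspecific},
#'   \code{gain_interstim}.
#' @param seed integer seed.
#' @return an object of class \code{"spike_raster"}: \code{spikes} (N x F binary
#'   integer matrix) and \code{frame_period_s}.
#' @export
simulate_raster <- function(ground_truth, schedule,
                            rates = list(),
                            seed = 1L) {
  stopifnot(inherits(ground_truth, "synthetic_ground_truth"),
            inherits(schedule, "stimulus_schedule"))
  r <- utils::modifyList(list(baseline = 0.02, gain = 10, suppression = 0.1,
                              gain_nontuned = 3, gain_unspecific = 3,
                              gain_interstim = 3), rates)
  if (r$baseline <= 0 || r$baseline >= 1) stopf("baseline rate must be in (0,1)")
  if (r$gain < 1) stopf("evoked gain must be >= 1")
  if (r$suppression < 0 || r$suppression > 1) stopf("suppression must be in [0,1]")

  N <- nrow(ground_truth$membership)
  F_ <- schedule$session_frames
  trials <- schedule$trials
  orient <- ground_truth$ensemble_orientations_deg
  tun <- ground_truth$tuning
  memb <- ground_truth$membership

  p <- matrix(r$baseline, N, F_)
  in_trial <- rep(FALSE, F_)

  with_seed(substream_seed(seed, "spikes"), {
    if (nrow(trials)) {
      for (t in seq_len(nrow(trials))) {
        fr <- (trials$onset_frame[t] + 1L):
          min(trials$onset_frame[t] + trials$duration_frames[t], F_)
        in_trial[fr] <- TRUE
        o <- direction_to_orientation(trials$direction_deg[t])
        e_match <- which(abs(orient - o) < 1e-9)
        on_i <- off_i <- integer(0)
        if (length(e_match)) {
          on_i <- which(apply(memb[, e_match, drop = FALSE] == "on", 1, any))
          off_i <- which(apply(memb[, e_match, drop = FALSE] == "off", 1, any))
          off_i <- setdiff(off_i, on_i)
        }
        participates <- stats::runif(N) <= ground_truth$reliability
        on_go <- on_i[participates[on_i]]
        p[on_go, fr] <- r$baseline * r$gain
        p[off_i, fr] <- r$baseline * r$suppression
        nt_i <- setdiff(which(tun$class == "pref" &
                                !is.na(tun$pref_orientation_deg) &
                                abs(tun$pref_orientation_deg - o) < 1e-9),
                        c(on_i, off_i))
        nt_go <- nt_i[participates[nt_i]]
        p[nt_go, fr] <- r$baseline * r$gain_nontuned
        un_i <- setdiff(which(tun$class == "unspecific"), c(on_i, off_i))
        p[un_i, fr] <- r$baseline * r$gain_unspecific
      }
    }
    inter_i <- which(tun$class == "interstim")
    if (length(inter_i) && any(!in_trial)) {
      p[inter_i, !in_trial] <- r$baseline * r$gain_interstim
    }
    if (any(p < 0 | p > 1)) {
      stopf("spike probabilities fall outside [0,1] after applying gains (max %.3f)",
            max(p))
    }
    spikes <- matrix(as.integer(stats::runif(N * F_) < p), N, F_)
    structure(list(spikes = spikes, frame_period_s = schedule$frame_period_s),
              class = "spike_raster")
  })
}

#' Synthesize GCaMP-like calcium traces from a spike raster
#'
#' Each spike adds an instantaneous-rise transient of per-neuron amplitude
#' that decays exponentially with the neuron's spontaneous decay constant;
#' during frames where one of the neuron's suppressing stimuli (an
#' orientation for which it is an offsemble member) is on, the decay constant
#' switches to the faster suppressed value. ROI fluorescence is the transient
#' signal plus \code{neuropil_level} times a shared slow background plus
#' white noise; the neuropil channel sees the background plus its own noise.
#'
#' @param true_raster a \code{"spike_raster"} from \code{\link{simulate_raster}}.
#' @param ground_truth the matching \code{"synthetic_ground_truth"}.
#' @param schedule the matching schedule, or NULL to disable
#'   suppressed-decay switching.
#' @param neuropil_level contamination factor of the shared background in the
#'   ROI channel.
#' @param noise_sd Gaussian noise s.d. added independently to both channels.
#' @param drift_amp amplitude of the slow sinusoidal background drift.
#' @param seed integer seed; noise uses its own substream, so two seeds give
#'   different noise but identical transient times for the same raster.
#' @return an object of class \code{"trace_set"}: \code{F_roi},
#'   \code{F_neuropil} (N x F matrices), \code{frame_period_s},
#'   \code{roi_positions}.
#' @export
synthesize_calcium <- function(true_raster, ground_truth, schedule = NULL,
                               neuropil_level = 1, noise_sd = 0.05,
                               drift_amp = 0.05, seed = 1L) {
  stopifnot(inherits(true_raster, "spike_raster"),
            inherits(ground_truth, "synthetic_ground_truth"))
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  kin <- ground_truth$kinetics
  if (any(kin$tau_decay_spont_s <= 0) || any(kin$tau_decay_suppressed_s <= 0)) {
    stopf("tau values must be > 0")
  }
  S <- true_raster$spikes
  N <- nrow(S); F_ <- ncol(S)
  dt <- true_raster$frame_period_s

  # per-neuron suppressing frames: trials of orientations the neuron is
  # an offsemble member of
  suppressed <- matrix(FALSE, N, F_)
  if (!is.null(schedule) && nrow(schedule$trials)) {
    memb <- ground_truth$membership
    orient <- ground_truth$ensemble_orientations_deg
    for (t in seq_len(nrow(schedule$trials))) {
      fr <- (schedule$trials$onset_frame[t] + 1L):
        min(schedule$trials$onset_frame[t] + schedule$trials$duration_frames[t], F_)
      o <- direction_to_orientation(schedule$trials$direction_deg[t])
      e_match <- which(abs(orient - o) < 1e-9)
      if (length(e_match)) {
        off_i <- which(apply(memb[, e_match, drop = FALSE] == "off", 1, any))
        suppressed[off_i, fr] <- TRUE
      }
    }
  }

  # shared slow background (deterministic drift around 1)
  tt <- seq_len(F_) * dt
  background <- 1 + drift_amp * sin(2 * pi * tt / 60)

  C <- matrix(0, N, F_)
  for (i in seq_len(N)) {
    dec_spont <- exp(-dt / kin$tau_decay_spont_s[i])
    dec_supp <- exp(-dt / kin$tau_decay_suppressed_s[i])
    ci <- 0
    a <- kin$amplitude[i]
    si <- S[i, ]; supi <- suppressed[i, ]
    row <- numeric(F_)
    for (f in seq_len(F_)) {
      ci <- ci * (if (supi[f]) dec_supp else dec_spont) + a * si[f]
      row[f] <- ci
    }
    C[i, ] <- row
  }

  with_seed(substream_seed(seed, "noise"), {
    noise_roi <- matrix(stats::rnorm(N * F_, sd = noise_sd), N, F_)
    noise_np <- matrix(stats::rnorm(N * F_, sd = noise_sd), N, F_)
    F_roi <- C + neuropil_level * matrix(background, N, F_, byrow = TRUE) + noise_roi
    F_np <- matrix(background, N, F_, byrow = TRUE) + noise_np
    positions <- data.frame(x = stats::runif(N, 0, 452),
                            y = stats::runif(N, 0, 452),
                            plane = sample(1:3, N, replace = TRUE))
    structure(list(F_roi = F_roi, F_neuropil = F_np,
                   frame_period_s = dt, roi_positions = positions),
              class = "trace_set")
  })
}

#' Simulate block-structured locomotion and whisking
#'
#' Running occurs in bouts (uniform 2-8 s) separated by still periods whose
#' mean length is set so running occupies approximately \code{run_fraction}
#' of the session; after construction the bout lengths are adjusted so the
#' occupancy matches the target to within one bout. Speed exceeds 1 cm/s in
#' running frames and stays below it otherwise. Whisking energy is elevated
#' during running bouts plus extra wakeful bouts up to
#' \code{whisk_fraction}.
#'
#' @param session_frames number of frames.
#' @param frame_period_s frame period in seconds.
#' @param run_fraction target fraction of running frames, in \[0,1\].
#' @param whisk_fraction target fraction of whisking frames (>= run_fraction
#'   is enforced by construction).
#' @param seed integer seed.
#' @return an object of class \code{"behavior_trace"}: \code{speed_cm_s} and
#'   \code{whisking_energy}, each of length \code{session_frames}.
#' @export
simulate_behavior <- function(session_frames, frame_period_s = 0.08,
                              run_fraction = 0.2, whisk_fraction = 0.34,
                              seed = 1L) {
  if (run_fraction < 0 || run_fraction > 1) stopf("run_fraction must be in [0,1]")
  F_ <- as.integer(session_frames)
  with_seed(substream_seed(seed, "behavior"), {
    running <- rep(FALSE, F_)
    if (run_fraction > 0) {
      target <- round(run_fraction * F_)
      bout_mean_s <- 5
      still_mean_s <- if (run_fraction >= 1) 0 else bout_mean_s * (1 - run_fraction) / run_fraction
      f <- 1L
      state_run <- FALSE
      while (f <= F_) {
        len_s <- if (state_run) stats::runif(1, 2, 8) else
          max(frame_period_s, stats::rexp(1, rate = 1 / max(still_mean_s, 1e-6)))
        len <- max(1L, round(len_s / frame_period_s))
        hi <- min(F_, f + len - 1L)
        if (state_run) running[f:hi] <- TRUE
        f <- hi + 1L
        state_run <- !state_run
      }
      # adjust occupancy toward the exact target by growing/shrinking bouts
      delta <- target - sum(running)
      guard <- 0L
      while (delta != 0L && guard < 10L * F_) {
        if (delta > 0L) {
          edge <- which(!running & c(running[-1], FALSE) | !running & c(FALSE, running[-F_]))
          if (!length(edge)) edge <- which(!running)
          if (!length(edge)) break
          running[edge[1]] <- TRUE; delta <- delta - 1L
        } else {
          edge <- which(running & !c(running[-1], TRUE) | running & !c(TRUE, running[-F_]))
          if (!length(edge)) edge <- which(running)
          if (!length(edge)) break
          running[edge[1]] <- FALSE; delta <- delta + 1L
        }
        guard <- guard + 1L
      }
    }
    speed <- numeric(F_)
    n_run <- sum(running)
    speed[!running] <- pmin(0.99, abs(stats::rnorm(F_ - n_run, 0.2, 0.2)))
    if (n_run) speed[running] <- 1 + abs(stats::rnorm(n_run, 4, 3))

    whisking <- running
    want <- round(min(1, max(whisk_fraction, run_fraction)) * F_)
    extra <- want - sum(whisking)
    f <- 1L
    while (extra > 0L && f <= F_) {
      if (!whisking[f] && stats::runif(1) < 0.02) {
        len <- min(extra, round(stats::runif(1, 2, 8) / frame_period_s))
        hi <- min(F_, f + len - 1L)
        newly <- sum(!whisking[f:hi])
        whisking[f:hi] <- TRUE
        extra <- extra - newly
        f <- hi
      }
      f <- f + 1L
    }
    energy <- 0.05 + abs(stats::rnorm(F_, 0, 0.02))
    energy[whisking] <- energy[whisking] + stats::runif(sum(whisking), 0.5, 1.5)
    structure(list(speed_cm_s = speed, whisking_energy = energy),
              class = "behavior_trace")
  })
}

#' Canonical synthetic study conditions
#'
#' Two frozen presets pairing a population configuration with per-frame
#' spiking rates:
#' \describe{
#'   \item{\code{"clean"}}{sparse spontaneous activity (0.002/frame),
#'     strongly driven onsembles (gain 150, fully reliable), total
#'     offsemble suppression, and no incidental tuning classes - the regime
#'     for recovery benchmarks where the planted structure should be found
#'     essentially exactly.}
#'   \item{\code{"paper"}}{the recording-like regime: moderate baseline
#'     (0.01/frame, ~0.12 Hz), evoked gain 25, partial suppression (0.1),
#'     45\% membership overlap between consecutive ensembles, offsembles
#'     drawn mostly (80\%) from other ensembles' onsemble members
#'     (cross-orientation suppression), imperfect trial-to-trial
#'     reliability (0.8 for members, 0.5 for tuned nonparticipants), and
#'     nonparticipant tuning classes present.}
#' }
#'
#' @param regime \code{"clean"} or \code{"paper"}.
#' @param n_neurons population size (default 200).
#' @return list with \code{config} (a \code{\link{synth_config}}) and
#'   \code{rates} (for \code{\link{simulate_raster}}).
#' @export
synth_regime <- function(regime = c("clean", "paper"), n_neurons = 200) {
  regime <- match.arg(regime)
  if (regime == "clean") {
    list(config = synth_config(n_neurons = n_neurons,
                               frac_non_pref = 0, frac_unspecific = 0,
                               frac_interstim = 0, overlap = 0,
                               off_from_on = 0.7),
         rates = list(baseline = 0.002, gain = 150, suppression = 0))
  } else {
    list(config = synth_config(n_neurons = n_neurons,
                               overlap = 0.45, off_from_on = 0.8,
                               reliability_on = 0.8, reliability_non = 0.5),
         rates = list(baseline = 0.01, gain = 25, suppression = 0.1))
  }
}
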