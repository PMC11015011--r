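#' File formats and pipeline orchestration
#'
#' Plain-text schemas: trace sets as CSV matrices plus a JSON metadata
#' sidecar, schedules and behavior as CSV, ground truth and p-values as
#' JSON, rasters as sparse (frame, neuron) CSV. Frame indices are 0-based
#' on disk (half-open stimulus intervals \[onset, onset + duration));
#' in-memory R objects use ordinary 1-based indexing.
#'
#' @name io
NULL

pipeline_defaults <- function() {
  list(
    schema_version = 1L,
    seed = 1L,
    # synthesis
    duration_s = 300, frame_period_s = 0.08, reps_min = 6,
    stim_dur_s = 2, isi_min_s = 1, isi_max_s = 5,
    n_neurons = 200, n_ensembles = 4,
    baseline_rate = 0.02, evoked_gain = 10, suppression = 0.1,
    neuropil_level = 1, noise_sd = 0.05, run_fraction = 0.2,
    # preprocessing
    psnr_min = 10, window_s = 0.5, tau_indicator_s = 5.8,
    epsilon_floor = 0.01,
    # detection
    k_min = 2L, k_max = 10L, n_surrogates = 1000L, n_iter = 1000L,
    alpha = 0.05,
    # behavior analysis
    run_threshold = 1, min_run_fraction = 0.05
  )
}

#' Validate a pipeline configuration
#'
#' Fills unspecified fields with defaults; unknown keys are rejected.
#'
#' @param config named list of overrides (possibly empty).
#' @return validated config list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(config = list()) {
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  out <- utils::modifyList(defaults, config)
  if (out$alpha <= 0 || out$alpha >= 1) stopf("alpha must be in (0,1)")
  if (out$frame_period_s <= 0) stopf("frame_period_s must be > 0")
  structure(out, class = "pipeline_config")
}

# stable short hash of a config (polynomial rolling hash of its canonical
# JSON, kept inside 31 bits)
config_hash <- function(config) {
  s <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE)
  h <- 7
  for (b in utf8ToInt(as.character(s))) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' @rdname io
#' @param schedule a \code{"stimulus_schedule"}.
#' @param path output CSV path; a \code{.json} metadata sidecar is written
#'   alongside.
#' @export
write_schedule_csv <- function(schedule, path) {
  utils::write.csv(schedule$trials, path, row.names = FALSE)
  jsonlite::write_json(list(frame_period_s = schedule$frame_period_s,
                            session_frames = schedule$session_frames),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname io
#' @export
read_schedule_csv <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(meta_path)) {
    stopf("schedule file or metadata sidecar missing: %s", path)
  }
  trials <- utils::read.csv(path)
  need <- c("onset_frame", "duration_frames", "direction_deg")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stopf("schedule CSV missing column(s): %s", paste(miss, collapse = ", "))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  structure(list(trials = trials, frame_period_s = meta$frame_period_s,
                 session_frames = as.integer(meta$session_frames)),
            class = "stimulus_schedule")
}

#' @rdname io
#' @param behavior a \code{"behavior_trace"}.
#' @export
write_behavior_csv <- function(behavior, path) {
  df <- data.frame(frame = seq_along(behavior$speed_cm_s) - 1L,
                   speed_cm_s = behavior$speed_cm_s,
                   whisking = behavior$whisking_energy)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_behavior_csv <- function(path) {
  df <- utils::read.csv(path)
  miss <- setdiff(c("frame", "speed_cm_s", "whisking"), names(df))
  if (length(miss)) stopf("behavior CSV missing column(s): %s", paste(miss, collapse = ", "))
  structure(list(speed_cm_s = df$speed_cm_s, whisking_energy = df$whisking),
            class = "behavior_trace")
}

#' @rdname io
#' @param ground_truth a \code{"synthetic_ground_truth"}.
#' @export
write_ground_truth_json <- function(ground_truth, path) {
  gt <- list(membership = apply(ground_truth$membership, 2, identity,
                                simplify = FALSE),
             tuning = ground_truth$tuning,
             kinetics = ground_truth$kinetics,
             reliability = ground_truth$reliability,
             ensemble_orientations_deg = ground_truth$ensemble_orientations_deg,
             seed = ground_truth$seed)
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a trace set as CSV matrices plus JSON metadata
#'
#' \code{F_roi.csv} and \code{F_neuropil.csv} hold one ROI per row;
#' \code{traces_meta.json} carries \code{frame_period_s} and ROI positions.
#'
#' @param traceset a \code{"trace_set"}.
#' @param dir output directory (created if needed).
#' @return the directory (write) or a \code{"trace_set"} (read).
#' @export
write_traces <- function(traceset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(traceset$F_roi, file.path(dir, "F_roi.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(traceset$F_neuropil, file.path(dir, "F_neuropil.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(frame_period_s = traceset$frame_period_s,
                            roi_positions = traceset$roi_positions),
                       file.path(dir, "traces_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_traces
#' @export
read_traces <- function(dir) {
  for (f in c("F_roi.csv", "F_neuropil.csv", "traces_meta.json")) {
    if (!file.exists(file.path(dir, f))) stopf("trace dataset missing: %s", f)
  }
  F_roi <- as.matrix(utils::read.table(file.path(dir, "F_roi.csv"), sep = ","))
  F_np <- as.matrix(utils::read.table(file.path(dir, "F_neuropil.csv"), sep = ","))
  dimnames(F_roi) <- dimnames(F_np) <- NULL
  if (!identical(dim(F_roi), dim(F_np))) stopf("trace matrices differ in shape")
  meta <- jsonlite::read_json(file.path(dir, "traces_meta.json"),
                              simplifyVector = TRUE)
  if (is.null(meta$frame_period_s)) stopf("traces_meta.json missing field frame_period_s")
  structure(list(F_roi = F_roi, F_neuropil = F_np,
                 frame_period_s = meta$frame_period_s,
                 roi_positions = as.data.frame(meta$roi_positions)),
            class = "trace_set")
}

#' @rdname io
#' @param raster a \code{"spike_raster"}.
#' @export
write_raster_csv <- function(raster, path) {
  idx <- which(raster$spikes != 0, arr.ind = TRUE)
  df <- data.frame(frame = idx[, 2] - 1L, neuron_id = idx[, 1] - 1L)
  df <- df[order(df$frame, df$neuron_id), ]
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(n_neurons = nrow(raster$spikes),
                            n_frames = ncol(raster$spikes),
                            frame_period_s = raster$frame_period_s),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname io
#' @export
read_raster_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path)
  m <- matrix(0L, meta$n_neurons, meta$n_frames)
  if (nrow(df)) m[cbind(df$neuron_id + 1L, df$frame + 1L)] <- 1L
  structure(list(spikes = m, frame_period_s = meta$frame_period_s),
            class = "spike_raster")
}

#' Run the whole analysis pipeline on a synthetic session
#'
#' simulate -> preprocess -> detect -> participate -> tune -> decode,
#' writing every stage's tables under \code{out_dir} together with a
#' provenance log (config hash, seed, package version). Rerunning with the
#' same config reproduces identical tables.
#'
#' @param config a \code{\link{pipeline_config}} (or list of overrides).
#' @param out_dir output directory.
#' @param verbose print per-stage progress counts.
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("pipeline"),
                         verbose = TRUE) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  say("[simulate] %d neurons, %.0f s session", cfg$n_neurons, cfg$duration_s)
  sim <- stage("simulate", {
    schedule <- generate_stimulus_schedule(
      cfg$duration_s, reps_min = cfg$reps_min, stim_dur_s = cfg$stim_dur_s,
      isi_min_s = cfg$isi_min_s, isi_max_s = cfg$isi_max_s,
      frame_period_s = cfg$frame_period_s, seed = cfg$seed)
    gt <- generate_population(synth_config(n_neurons = cfg$n_neurons,
                                           n_ensembles = cfg$n_ensembles),
                              seed = cfg$seed)
    raster_true <- simulate_raster(gt, schedule,
                                   rates = list(baseline = cfg$baseline_rate,
                                                gain = cfg$evoked_gain,
                                                suppression = cfg$suppression),
                                   seed = cfg$seed)
    traces <- synthesize_calcium(raster_true, gt, schedule,
                                 neuropil_level = cfg$neuropil_level,
                                 noise_sd = cfg$noise_sd, seed = cfg$seed)
    behavior <- simulate_behavior(schedule$session_frames,
                                  frame_period_s = cfg$frame_period_s,
                                  run_fraction = cfg$run_fraction,
                                  seed = cfg$seed)
    list(schedule = schedule, gt = gt, raster_true = raster_true,
         traces = traces, behavior = behavior)
  })
  write_schedule_csv(sim$schedule, file.path(out_dir, "schedule.csv"))
  write_behavior_csv(sim$behavior, file.path(out_dir, "behavior.csv"))
  write_ground_truth_json(sim$gt, file.path(out_dir, "ground_truth.json"))

  pre <- stage("preprocess", preprocess_traces(
    sim$traces, psnr_min = cfg$psnr_min, window_s = cfg$window_s,
    tau_indicator_s = cfg$tau_indicator_s, epsilon_floor = cfg$epsilon_floor))
  say("[preprocess] %d/%d ROIs passed QC", sum(pre$qc$passed), nrow(pre$qc))
  utils::write.csv(pre$qc, file.path(out_dir, "qc.csv"), row.names = FALSE)
  write_raster_csv(pre$raster, file.path(out_dir, "raster.csv"))

  fit <- stage("detect", detect_ensembles(
    pre$raster, k_min = cfg$k_min, k_max = cfg$k_max,
    n_surrogates = cfg$n_surrogates, n_iter = cfg$n_iter,
    alpha = cfg$alpha, seed = cfg$seed))
  say("[detect] %d clustered frames, k* = %d, %d significant ensembles",
      length(fit$frames), fit$n_clusters, length(fit$ensemble_ids))
  frame_tab <- data.frame(frame = fit$frames - 1L, cluster = fit$frame_labels,
                          is_ensemble = fit$frame_labels %in% fit$ensemble_ids)
  utils::write.csv(frame_tab, file.path(out_dir, "frame_labels.csv"),
                   row.names = FALSE)
  jsonlite::write_json(as.list(fit$cluster_pvalues),
                       file.path(out_dir, "cluster_pvalues.json"),
                       auto_unbox = TRUE, digits = NA)

  part <- stage("participate", participation_all(fit, pre$raster, alpha = cfg$alpha))
  say("[participate] %d onsemble / %d offsemble labels",
      sum(part$class == "onsemble"), sum(part$class == "offsemble"))
  utils::write.csv(part[, c("neuron_id", "ensemble_id", "epi", "p_value", "class")],
                   file.path(out_dir, "participation.csv"), row.names = FALSE)

  tune <- stage("tune", {
    etab <- ensemble_tuning(fit, sim$schedule, alpha = cfg$alpha)
    cells <- lapply(seq_len(nrow(pre$raster$spikes)), function(i) {
      classify_cell_tuning(pre$raster$spikes[i, ], sim$schedule, alpha = cfg$alpha)
    })
    cell_tab <- data.frame(
      neuron_id = seq_along(cells),
      class = vapply(cells, `[[`, character(1), "class"),
      theta_pref_deg = vapply(cells, `[[`, numeric(1), "theta_pref_deg"),
      p = vapply(cells, `[[`, numeric(1), "p"))
    list(ensembles = etab, cells = cell_tab)
  })
  say("[tune] %d/%d ensembles orientation-tuned; %d tuned neurons",
      sum(tune$ensembles$significant), nrow(tune$ensembles),
      sum(tune$cells$class == "tuned"))
  utils::write.csv(tune$ensembles, file.path(out_dir, "ensemble_tuning.csv"),
                   row.names = FALSE)
  utils::write.csv(tune$cells, file.path(out_dir, "cell_tuning.csv"),
                   row.names = FALSE)

  dec <- stage("decode", {
    tuned_e <- tune$ensembles[tune$ensembles$significant, , drop = FALSE]
    true_or <- direction_to_orientation(sim$schedule$trials$direction_deg)
    ens_report <- NULL
    orients <- sort(unique(true_or))
    if (length(orients) == 4 &&
        all(vapply(orients, function(o)
          any(abs(wrap_orientation(tuned_e$theta_pref_deg - o)) < 22.5),
          logical(1)))) {
      rows <- vapply(orients, function(o) {
        eid <- tuned_e$ensemble_id[
          which.min(abs(wrap_orientation(tuned_e$theta_pref_deg - o)))]
        trial_responses(fit$signals[as.character(eid) == rownames(fit$signals), ],
                        sim$schedule)$response
      }, numeric(nrow(sim$schedule$trials)))
      rm_ <- t(rows); rownames(rm_) <- orients
      ens_report <- decode_orientations(rm_, true_or, seed = cfg$seed)
    }
    ens_report
  })
  if (!is.null(dec)) {
    say("[decode] ensemble decoding accuracy %.3f", dec$accuracy)
    cm <- as.data.frame(as.table(dec$matrix))
    names(cm) <- c("true", "predicted", "count")
    utils::write.csv(cm, file.path(out_dir, "confusion_ensembles.csv"),
                     row.names = FALSE)
  }

  prov <- list(config = unclass(cfg), config_hash = config_hash(unclass(cfg)),
               package_version = as.character(utils::packageVersion("onsembles")),
               r_version = R.version.string,
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(config = cfg, sim = sim, preprocess = pre, fit = fit,
                 participation = part, tuning = tune, decoding = dec,
                 out_dir = out_dir))
}
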