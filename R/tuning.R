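#' Orientation tuning of neurons, ensembles and member groups
#'
#' Trial responses are mean activity over each 2-s stimulus window, in
#' \[0, 1\] for every unit kind. Orientation selectivity is 1 - circular
#' variance with doubled angles; significance comes from a one-sample
#' Hotelling t-squared test on the doubled-angle response vectors; tuning
#' width from a bounded Gaussian fit over orientation.
#'
#' @name tuning
NULL

#' Group activity series for ensemble member populations
#'
#' Per frame: the fraction of group members active (onsemble, offsemble,
#' nonparticipant-tuned), or for the combined ensemble-member criterion
#' (\code{"ensemble_dagger"}) the fraction of members "participating" -
#' active onsemble members plus \emph{inactive} offsemble members over the
#' total onsemble + offsemble size.
#'
#' @param raster a \code{"spike_raster"} (or binary matrix).
#' @param participation a \code{\link{classify_participation}} table for one
#'   ensemble.
#' @param group one of \code{"onsemble"}, \code{"offsemble"},
#'   \code{"nonparticipant_tuned"}, \code{"ensemble_dagger"}.
#' @param tuned_ids neuron ids with significant orientation tuning; required
#'   for \code{"nonparticipant_tuned"}.
#' @return object of class \code{"group_activity"}: \code{series} in
#'   \[0, 1\] per frame, \code{group}, \code{members}.
#' @export
group_activity <- function(raster, participation, group,
                           tuned_ids = NULL) {
  X <- if (inherits(raster, "spike_raster")) raster$spikes else raster
  group <- match.arg(group, c("onsemble", "offsemble",
                              "nonparticipant_tuned", "ensemble_dagger"))
  on_i <- participation$neuron_id[participation$class == "onsemble"]
  off_i <- participation$neuron_id[participation$class == "offsemble"]
  if (group == "ensemble_dagger") {
    n_tot <- length(on_i) + length(off_i)
    if (n_tot == 0) stopf("ensemble has no onsemble or offsemble members")
    act_on <- if (length(on_i)) colSums(X[on_i, , drop = FALSE]) else 0
    inact_off <- if (length(off_i)) {
      length(off_i) - colSums(X[off_i, , drop = FALSE])
    } else 0
    series <- (act_on + inact_off) / n_tot
    members <- c(on_i, off_i)
  } else {
    members <- switch(group,
      onsemble = on_i,
      offsemble = off_i,
      nonparticipant_tuned = {
        if (is.null(tuned_ids)) stopf("tuned_ids required for nonparticipant_tuned")
        intersect(participation$neuron_id[participation$class == "nonparticipant"],
                  tuned_ids)
      })
    if (length(members) == 0) stopf("empty %s group", group)
    series <- colMeans(X[members, , drop = FALSE])
  }
  structure(list(series = series, group = group, members = members),
            class = "group_activity")
}

#' Per-trial responses of an activity series
#'
#' Mean of the series over each trial's stimulus frames; responses are in
#' \[0, 1\] for binary and fraction-valued series alike.
#'
#' @param activity_series numeric series over frames (binary neuron or
#'   ensemble signal, or group fraction), or a \code{"group_activity"}.
#' @param schedule a \code{"stimulus_schedule"}.
#' @return data.frame of class \code{"trial_responses"}: \code{trial},
#'   \code{direction_deg}, \code{orientation_deg}, \code{response}.
#' @export
trial_responses <- function(activity_series, schedule) {
  if (inherits(activity_series, "group_activity")) {
    activity_series <- activity_series$series
  }
  tr <- schedule$trials
  F_ <- length(activity_series)
  if (nrow(tr) && any(tr$onset_frame + tr$duration_frames > F_)) {
    stopf("trial extends past the end of the session")
  }
  resp <- vapply(seq_len(nrow(tr)), function(t) {
    fr <- (tr$onset_frame[t] + 1L):(tr$onset_frame[t] + tr$duration_frames[t])
    mean(activity_series[fr])
  }, numeric(1))
  out <- data.frame(trial = seq_len(nrow(tr)),
                    direction_deg = tr$direction_deg,
                    orientation_deg = direction_to_orientation(tr$direction_deg),
                    response = resp)
  class(out) <- c("trial_responses", "data.frame")
  out
}

#' Orientation selectivity (1 - circular variance) and preferred orientation
#'
#' With mean response R_k at orientation theta_k, selectivity is
#' \code{|sum R_k exp(i 2 theta_k)| / sum R_k} (angle doubling, the standard
#' orientation-domain convention) and the preferred orientation is half the
#' argument of the sum, mapped to \[0, 180).
#'
#' @param tr a \code{"trial_responses"} data.frame.
#' @return list with \code{osi} in \[0, 1\], \code{theta_pref_deg}, and the
#'   per-orientation \code{means}; all NA when every response is zero.
#' @export
orientation_selectivity <- function(tr) {
  means <- tapply(tr$response, tr$orientation_deg, mean)
  thetas <- as.numeric(names(means))
  if (all(means == 0)) {
    return(list(osi = NA_real_, theta_pref_deg = NA_real_, means = means))
  }
  z <- sum(means * exp(2i * thetas * pi / 180))
  osi <- Mod(z) / sum(means)
  theta <- (Arg(z) / 2) * 180 / pi
  theta <- theta %% 180
  list(osi = osi, theta_pref_deg = theta, means = means)
}

#' One-sample Hotelling t-squared test of orientation tuning
#'
#' Each trial is mapped to the doubled-angle vector
#' \code{R_t (cos 2 theta_t, sin 2 theta_t)}; the test asks whether the mean
#' vector differs from (0, 0), with p from the F reference distribution.
#' Singular covariance falls back to a label-permutation exceedance test on
#' the mean resultant length (flagged).
#'
#' @param tr a \code{"trial_responses"} data.frame with >= 3 trials.
#' @param n_perm permutations used by the singular-covariance fallback.
#' @return list with \code{p}, \code{t2} and \code{flagged}.
#' @export
hotelling_test <- function(tr, n_perm = 999) {
  n <- nrow(tr)
  if (n < 3) stopf("Hotelling test needs >= 3 trials")
  ang <- 2 * tr$orientation_deg * pi / 180
  V <- cbind(tr$response * cos(ang), tr$response * sin(ang))
  if (all(tr$response == 0)) {
    return(list(p = 1, t2 = 0, flagged = TRUE))
  }
  m <- colMeans(V)
  S <- stats::cov(V)
  t2 <- tryCatch(n * drop(t(m) %*% solve(S) %*% m), error = function(e) NA_real_)
  if (is.finite(t2)) {
    f <- (n - 2) / (2 * (n - 1)) * t2
    p <- stats::pf(f, 2, n - 2, lower.tail = FALSE)
    return(list(p = p, t2 = t2, flagged = FALSE))
  }
  obs <- sqrt(sum(m^2))
  null <- with_seed(1L, vapply(seq_len(n_perm), function(b) {
    a2 <- sample(ang)
    sqrt(sum(colMeans(cbind(tr$response * cos(a2), tr$response * sin(a2)))^2))
  }, numeric(1)))
  list(p = (1 + sum(null >= obs)) / (n_perm + 1), t2 = NA_real_, flagged = TRUE)
}

# wrapped orientation difference, mapped to [-90, 90)
wrap_orientation <- function(d) ((d + 90) %% 180) - 90

#' Bounded Gaussian tuning-curve fit over orientation
#'
#' Nonlinear least squares of
#' \code{a * exp(-wrap(theta - theta_pref)^2 / (2 sigma^2))} with the
#' orientation difference wrapped to \[-90, 90) and coefficients bounded to
#' a in \[0, 1\], theta_pref in \[-45, 180\] and sigma in \[1, 90\] degrees.
#' Fits are multi-started over the observed orientations; a fit resting on a
#' bound is flagged.
#'
#' @param orientation_means named numeric vector of mean responses, names
#'   are orientations in degrees (>= 4 values).
#' @return list with \code{a}, \code{theta_pref_deg}, \code{sigma_deg},
#'   \code{rss}, \code{at_bound}.
#' @export
fit_tuning_curve <- function(orientation_means) {
  if (length(orientation_means) < 4) stopf("need >= 4 orientation means")
  theta <- as.numeric(names(orientation_means))
  y <- as.numeric(orientation_means)
  model <- function(p) p[1] * exp(-wrap_orientation(theta - p[2])^2 / (2 * p[3]^2))
  lower <- c(0, -45, 1); upper <- c(1, 180, 90)
  best <- NULL
  starts <- unique(c(theta[which.max(y)], theta))
  for (th0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(a = min(max(max(y), 1e-3), 1), theta_pref = th0, sigma = 30),
        lower = lower, upper = upper,
        fn = function(p) y - model(p),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-15) {
      best <- list(par = fit$par, rss = rss)
    }
  }
  if (is.null(best)) stopf("tuning-curve fit failed")
  p <- best$par
  at_bound <- any(abs(p - lower) < 1e-6) || any(abs(p - upper) < 1e-6)
  list(a = unname(p[1]), theta_pref_deg = unname(p[2]),
       sigma_deg = unname(p[3]), rss = best$rss, at_bound = at_bound)
}

#' Full tuning characterization of one unit
#'
#' Selectivity (1 - CirVar), Hotelling significance, and the bounded
#' Gaussian tuning-curve fit.
#'
#' @param tr a \code{"trial_responses"} data.frame.
#' @param alpha significance level for the Hotelling test.
#' @return object of class \code{"tuning_result"}: \code{osi},
#'   \code{theta_pref_deg}, \code{hotelling_p}, \code{significant},
#'   \code{curve} (a, theta_pref_deg, sigma_deg), \code{fit_rss}.
#' @export
unit_tuning <- function(tr, alpha = 0.05) {
  sel <- orientation_selectivity(tr)
  ht <- hotelling_test(tr)
  curve <- if (all(is.na(sel$means)) || all(sel$means == 0)) {
    list(a = NA_real_, theta_pref_deg = NA_real_, sigma_deg = NA_real_,
         rss = NA_real_, at_bound = TRUE)
  } else fit_tuning_curve(sel$means)
  structure(list(osi = sel$osi, theta_pref_deg = sel$theta_pref_deg,
                 hotelling_p = ht$p, significant = !is.na(ht$p) && ht$p < alpha,
                 curve = curve, fit_rss = curve$rss,
                 orientation_means = sel$means),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("Tuning: osi = %.3f, theta_pref = %.1f deg, p = %.3g%s; width sigma = %.1f deg\n",
              x$osi, x$theta_pref_deg, x$hotelling_p,
              if (x$significant) " (significant)" else "",
              x$curve$sigma_deg))
  invisible(x)
}

#' Tuning of every significant ensemble in a fit
#'
#' @param fit an \code{"ensemble_fit"}.
#' @param schedule the session's stimulus schedule.
#' @param alpha Hotelling significance level.
#' @return data.frame: \code{ensemble_id}, \code{osi},
#'   \code{theta_pref_deg}, \code{p}, \code{significant}, \code{a},
#'   \code{sigma_deg}.
#' @export
ensemble_tuning <- function(fit, schedule, alpha = 0.05) {
  rows <- lapply(seq_along(fit$ensemble_ids), function(i) {
    tr <- trial_responses(fit$signals[i, ], schedule)
    tu <- unit_tuning(tr, alpha = alpha)
    data.frame(ensemble_id = fit$ensemble_ids[i], osi = tu$osi,
               theta_pref_deg = tu$theta_pref_deg, p = tu$hotelling_p,
               significant = tu$significant, a = tu$curve$a,
               sigma_deg = tu$curve$sigma_deg)
  })
  do.call(rbind, rows)
}

# activity criterion for "active at this frame": strictly above 0 for
# binary series, above the session median for fraction-valued group series
default_activity_criterion <- function(series) {
  if (all(series %in% c(0, 1))) 0 else stats::median(series)
}

#' Trial-to-trial activation probability at the preferred orientation
#'
#' Per relative frame within the stimulus window, the fraction of
#' preferred-orientation trials in which the unit is active (series above
#' its activity criterion: 0 for binary units, the session median for
#' fraction-valued group series).
#'
#' @param activity_series numeric series (or \code{"group_activity"}).
#' @param schedule the stimulus schedule.
#' @param theta_pref preferred orientation in degrees.
#' @param criterion activity criterion; NULL for the default.
#' @return list with \code{prob} (per relative frame), \code{time_s},
#'   \code{max}, \code{latency_s}, \code{n_trials}.
#' @export
activation_probability <- function(activity_series, schedule, theta_pref,
                                   criterion = NULL) {
  if (inherits(activity_series, "group_activity")) {
    activity_series <- activity_series$series
  }
  if (is.null(criterion)) criterion <- default_activity_criterion(activity_series)
  tr <- schedule$trials
  sel <- which(abs(direction_to_orientation(tr$direction_deg) - theta_pref) < 1e-9)
  if (length(sel) == 0) stopf("no trials at theta_pref = %g deg", theta_pref)
  if (length(sel) < 2) stopf("need >= 2 trials at theta_pref")
  nf <- min(tr$duration_frames[sel])
  act <- vapply(sel, function(t) {
    fr <- (tr$onset_frame[t] + 1L):(tr$onset_frame[t] + nf)
    as.numeric(activity_series[fr] > criterion)
  }, numeric(nf))
  prob <- rowMeans(act)
  dt <- schedule$frame_period_s
  list(prob = prob, time_s = (seq_len(nf) - 1) * dt,
       max = max(prob), latency_s = (which.max(prob) - 1) * dt,
       n_trials = length(sel))
}

#' Mean duration of continuous evoked activity at the preferred orientation
#'
#' Per preferred-orientation trial: the length (seconds) of the first
#' maximal run of supra-criterion activity starting at or after stimulus
#' onset (0 when none occurs), averaged over trials.
#'
#' @inheritParams activation_probability
#' @return mean duration in seconds.
#' @export
evoked_duration <- function(activity_series, schedule, theta_pref,
                            criterion = NULL) {
  if (inherits(activity_series, "group_activity")) {
    activity_series <- activity_series$series
  }
  if (is.null(criterion)) criterion <- default_activity_criterion(activity_series)
  tr <- schedule$trials
  sel <- which(abs(direction_to_orientation(tr$direction_deg) - theta_pref) < 1e-9)
  if (length(sel) == 0) stopf("no trials at theta_pref = %g deg", theta_pref)
  dt <- schedule$frame_period_s
  F_ <- length(activity_series)
  active <- activity_series > criterion
  durs <- vapply(sel, function(t) {
    f0 <- tr$onset_frame[t] + 1L
    start <- f0
    while (start <= F_ && !active[start]) start <- start + 1L
    if (start > F_) return(0)
    end <- start
    while (end < F_ && active[end + 1L]) end <- end + 1L
    (end - start + 1L) * dt
  }, numeric(1))
  mean(durs)
}

#' Single-cell tuning class
#'
#' A neuron with significant orientation selectivity (Hotelling p < alpha)
#' is tuned to its preferred orientation. Otherwise, per-period mean
#' activity during stimulation vs interstimulus periods is compared by a
#' two-sample t-test: significantly higher during stimulation = unspecific;
#' significantly higher between stimuli = interstim; otherwise untuned.
#'
#' @param neuron_spikes binary spike series.
#' @param schedule the stimulus schedule (must leave both stimulation and
#'   interstimulus frames within the session).
#' @param alpha significance level.
#' @return list with \code{class} in
#'   \{"tuned","unspecific","interstim","untuned"\}, \code{theta_pref_deg}
#'   (NA unless tuned), \code{p}.
#' @export
classify_cell_tuning <- function(neuron_spikes, schedule, alpha = 0.05) {
  tr <- schedule$trials
  if (nrow(tr) == 0) stopf("schedule has no trials")
  F_ <- length(neuron_spikes)
  stim <- rep(FALSE, F_)
  for (t in seq_len(nrow(tr))) {
    stim[(tr$onset_frame[t] + 1L):min(tr$onset_frame[t] + tr$duration_frames[t], F_)] <- TRUE
  }
  if (!any(!stim)) stopf("no interstimulus frames in the session")
  resp <- trial_responses(neuron_spikes, schedule)
  ht <- hotelling_test(resp)
  if (!is.na(ht$p) && ht$p < alpha && any(resp$response > 0)) {
    sel <- orientation_selectivity(resp)
    return(list(class = "tuned", theta_pref_deg = sel$theta_pref_deg, p = ht$p))
  }
  # per-period samples: one mean per trial, one per interstimulus gap
  stim_samples <- resp$response
  gaps <- runs_of_ones(as.integer(!stim))
  isi_samples <- vapply(seq_len(nrow(gaps)),
                        function(j) mean(neuron_spikes[gaps$start[j]:gaps$end[j]]),
                        numeric(1))
  tt <- tryCatch(stats::t.test(stim_samples, isi_samples),
                 error = function(e) NULL)
  if (is.null(tt) || is.na(tt$p.value) || tt$p.value >= alpha) {
    return(list(class = "untuned", theta_pref_deg = NA_real_,
                p = if (is.null(tt)) NA_real_ else tt$p.value))
  }
  cls <- if (mean(stim_samples) > mean(isi_samples)) "unspecific" else "interstim"
  list(class = cls, theta_pref_deg = NA_real_, p = tt$p.value)
}

#' Composition of ensemble memberships by single-cell tuning class
#'
#' Per ensemble, counts of onsemble / offsemble / nonparticipant members
#' whose single-cell class is: tuned to the ensemble's preferred orientation
#' (pref), tuned to a different orientation (nonpref), unspecific,
#' interstim, or untuned; plus counts of neurons shared across multiple
#' onsembles and across multiple offsembles.
#'
#' @param participation a \code{\link{participation_all}} table (with
#'   \code{ensemble_id}).
#' @param cell_classes data.frame per neuron: \code{class},
#'   \code{theta_pref_deg} (from \code{\link{classify_cell_tuning}}).
#' @param ensemble_orientations named numeric vector: preferred orientation
#'   per ensemble id (NA for untuned ensembles).
#' @return list with \code{composition} (data.frame ensemble_id, group,
#'   pref, nonpref, unspecific, interstim, untuned) and \code{shared}
#'   (neurons in >= 2 onsembles / offsembles).
#' @export
ensemble_composition <- function(participation, cell_classes,
                                 ensemble_orientations) {
  eids <- unique(participation$ensemble_id)
  rows <- list()
  for (e in eids) {
    sub <- participation[participation$ensemble_id == e, ]
    e_or <- ensemble_orientations[as.character(e)]
    for (g in c("onsemble", "offsemble", "nonparticipant")) {
      ids <- sub$neuron_id[sub$class == g]
      cc <- cell_classes[ids, , drop = FALSE]
      is_tuned <- cc$class == "tuned"
      pref <- is_tuned & !is.na(e_or) &
        abs(wrap_orientation(cc$theta_pref_deg - e_or)) < 22.5
      rows[[length(rows) + 1L]] <- data.frame(
        ensemble_id = e, group = g,
        pref = sum(pref, na.rm = TRUE),
        nonpref = sum(is_tuned & !pref, na.rm = TRUE),
        unspecific = sum(cc$class == "unspecific"),
        interstim = sum(cc$class == "interstim"),
        untuned = sum(cc$class == "untuned"))
    }
  }
  comp <- do.call(rbind, rows)
  on_counts <- table(participation$neuron_id[participation$class == "onsemble"])
  off_counts <- table(participation$neuron_id[participation$class == "offsemble"])
  list(composition = comp,
       shared = list(onsemble = sum(on_counts >= 2),
                     offsemble = sum(off_counts >= 2)))
}
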