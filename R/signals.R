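#' Fluorescence preprocessing: from raw traces to a binary raster
#'
#' Implements the extraction chain: neuropil normalization, PSNR-based ROI
#' quality control, median/min/max morphological smoothing, sparse
#' nonnegative AR(1) spike deconvolution, and PSNR-proportional binarization,
#' plus exponential decay-constant fitting of calcium transients.
#'
#' @name signals
NULL

#' Neuropil-normalized fluorescence
#'
#' \code{(F_ROI - F_neuropil) / F_neuropil}, elementwise. Accepts vectors
#' (one ROI) or matrices (ROIs in rows).
#'
#' @param F_ROI,F_neuropil raw ROI and local-neuropil fluorescence, equal
#'   dimensions.
#' @param eps division guard: any \code{|F_neuropil| < eps} raises an error
#'   naming the offending ROI.
#' @return the filtered trace(s), same shape as the input.
#' @export
neuropil_correct <- function(F_ROI, F_neuropil, eps = 1e-3) {
  if (!identical(dim(F_ROI), dim(F_neuropil)) ||
      length(F_ROI) != length(F_neuropil)) {
    stopf("F_ROI and F_neuropil must have identical shape")
  }
  small <- abs(F_neuropil) < eps
  if (any(small)) {
    bad <- if (is.matrix(F_neuropil)) unique(which(small, arr.ind = TRUE)[, 1]) else 1L
    stopf("neuropil signal within %g of zero for ROI(s) %s",
          eps, paste(bad, collapse = ", "))
  }
  (F_ROI - F_neuropil) / F_neuropil
}

#' Peak signal-to-noise ratio of an ROI trace, in dB
#'
#' \code{20 * log10(max(F_ROI - F_neuropil) / sd(F_neuropil))}. A
#' nonpositive peak difference yields \code{-Inf} (the ROI then fails QC).
#'
#' @inheritParams neuropil_correct
#' @return PSNR in decibels (scalar for vectors, one value per row for
#'   matrices).
#' @export
compute_psnr <- function(F_ROI, F_neuropil) {
  one <- function(fr, fn) {
    s <- stats::sd(fn)
    if (!is.finite(s) || s == 0) stopf("neuropil trace has zero variance")
    peak <- max(fr - fn)
    if (peak <= 0) return(-Inf)
    20 * log10(peak / s)
  }
  if (is.matrix(F_ROI)) {
    vapply(seq_len(nrow(F_ROI)),
           function(i) one(F_ROI[i, ], F_neuropil[i, ]), numeric(1))
  } else one(F_ROI, F_neuropil)
}

#' Select ROIs by PSNR and record binarization thresholds
#'
#' Keeps ROIs whose PSNR strictly exceeds \code{psnr_min} (default 10 dB)
#' and records, per ROI, the binarization threshold
#' \code{max(0.04 - 0.002 * PSNR, epsilon_floor)}.
#'
#' @param traceset a \code{"trace_set"} (fields \code{F_roi},
#'   \code{F_neuropil}, \code{frame_period_s}).
#' @param psnr_min QC cutoff in dB; comparison is strict (\code{>}) by
#'   default.
#' @param strict use \code{>} (TRUE, default) or \code{>=}.
#' @param epsilon_floor lower floor for the binarization threshold, so that a
#'   high-PSNR ROI's nonzero inferred spikes are still required to exceed a
#'   positive value.
#' @return list with \code{traceset} (surviving rows, with \code{F_filtered}
#'   added) and \code{qc} (data.frame \code{roi_id}, \code{psnr_db},
#'   \code{passed}, \code{threshold}).
#' @export
select_rois <- function(traceset, psnr_min = 10, strict = TRUE,
                        epsilon_floor = 0.01) {
  stopifnot(inherits(traceset, "trace_set"))
  psnr <- compute_psnr(traceset$F_roi, traceset$F_neuropil)
  passed <- if (strict) psnr > psnr_min else psnr >= psnr_min
  qc <- data.frame(roi_id = seq_along(psnr), psnr_db = psnr, passed = passed,
                   threshold = pmax(0.04 - 0.002 * psnr, epsilon_floor))
  if (!any(passed)) stopf("no ROI passed QC at psnr_min = %g dB", psnr_min)
  keep <- which(passed)
  out <- traceset
  out$F_roi <- traceset$F_roi[keep, , drop = FALSE]
  out$F_neuropil <- traceset$F_neuropil[keep, , drop = FALSE]
  out$F_filtered <- neuropil_correct(out$F_roi, out$F_neuropil)
  if (!is.null(traceset$roi_positions)) {
    out$roi_positions <- traceset$roi_positions[keep, , drop = FALSE]
  }
  out$qc <- qc
  list(traceset = out, qc = qc)
}

#' Morphological smoothing of a fluorescence trace
#'
#' Sequential moving median, moving minimum, and moving maximum, each with
#' the same centered window of an odd number of frames
#' (\code{round(window_s / frame_period_s)}, forced odd; edges handled by
#' window truncation). The min-then-max pair is a morphological opening:
#' events shorter than the window are removed, while onset times of longer
#' transients are preserved.
#'
#' @param x numeric trace (one ROI).
#' @param window_s window length in seconds (default 0.5).
#' @param frame_period_s frame period in seconds.
#' @return smoothed trace, same length.
#' @export
smooth_trace <- function(x, window_s = 0.5, frame_period_s = 0.08) {
  if (window_s < frame_period_s) stopf("window_s must be >= frame_period_s")
  k <- odd_window_frames(window_s, frame_period_s)
  x <- roll_filter(x, k, stats::median)
  x <- roll_filter(x, k, min)
  roll_filter(x, k, max)
}

#' Sparse nonnegative spike deconvolution (AR(1) model)
#'
#' Solves \deqn{\min_c \frac12\|c-y\|^2 + \lambda \sum_t s_t,\quad
#' s_t = c_t - \gamma c_{t-1} \ge 0} by the pool-adjacent-violators
#' (OASIS-style) algorithm, i.e. the "foopsi" sparse deconvolution under a
#' first-order autoregressive calcium model. The trace is baseline-corrected
#' by subtracting its 8th percentile before solving.
#'
#' @param y numeric trace (typically smoothed neuropil-normalized
#'   fluorescence).
#' @param gamma AR(1) decay factor per frame, in (0,1); for an indicator
#'   decay constant tau this is \code{exp(-frame_period_s / tau)}.
#' @param lam nonnegative sparsity penalty; \code{NULL} (default) uses a
#'   noise estimate, \code{mad(diff(y)) / sqrt(2)}.
#' @param baseline_correct subtract the 8th-percentile baseline first
#'   (default TRUE).
#' @return nonnegative spike-rate series \code{s}, same length as \code{y}.
#' @export
infer_spikes <- function(y, gamma, lam = NULL, baseline_correct = TRUE) {
  if (gamma <= 0 || gamma >= 1) stopf("gamma must be in (0,1)")
  if (is.null(lam)) lam <- stats::mad(diff(y)) / sqrt(2)
  if (lam < 0) stopf("lam must be >= 0")
  if (baseline_correct) y <- y - stats::quantile(y, 0.08, names = FALSE)
  n <- length(y)
  if (n == 0) return(numeric(0))
  # fold the L1 penalty into the data: lambda * sum(s) = sum_t mu_t * c_t
  # with mu_t = 1 - gamma for t < n and mu_n = 1
  ytil <- y - lam * (1 - gamma)
  ytil[n] <- y[n] - lam

  # pools: value v, weight w, start t, length l; within a pool
  # c_t = max(0, v/w) * gamma^(t - start)
  v <- numeric(n); w <- numeric(n); tstart <- integer(n); len <- integer(n)
  np <- 0L
  for (t in seq_len(n)) {
    np <- np + 1L
    v[np] <- ytil[t]; w[np] <- 1; tstart[np] <- t; len[np] <- 1L
    while (np > 1L &&
           v[np] / w[np] < gamma^len[np - 1L] * v[np - 1L] / w[np - 1L]) {
      g <- gamma^len[np - 1L]
      v[np - 1L] <- v[np - 1L] + g * v[np]
      w[np - 1L] <- w[np - 1L] + g^2 * w[np]
      len[np - 1L] <- len[np - 1L] + len[np]
      np <- np - 1L
    }
  }
  c_hat <- numeric(n)
  for (p in seq_len(np)) {
    c0 <- max(0, v[p] / w[p])
    idx <- tstart[p]:(tstart[p] + len[p] - 1L)
    c_hat[idx] <- c0 * gamma^(seq_along(idx) - 1L)
  }
  s <- c(c_hat[1], c_hat[-1] - gamma * c_hat[-n])
  s[s < 1e-12] <- 0
  s
}

#' Binarize an inferred spike series by a PSNR-proportional threshold
#'
#' Threshold is \code{max(0.04 - 0.002 * psnr_db, epsilon_floor)}; output is
#' 1 where the spike series strictly exceeds it.
#'
#' @param spike_series nonnegative series from \code{\link{infer_spikes}}.
#' @param psnr_db the ROI's PSNR in dB (finite).
#' @param epsilon_floor threshold floor (default 0.01).
#' @return integer 0/1 series.
#' @export
binarize_spikes <- function(spike_series, psnr_db, epsilon_floor = 0.01) {
  if (!is.finite(psnr_db)) stopf("psnr_db must be finite")
  thr <- max(0.04 - 0.002 * psnr_db, epsilon_floor)
  as.integer(spike_series > thr)
}

#' Stack per-ROI binary series into an N x F raster
#'
#' @param binary list of equal-length 0/1 vectors (or an N x F matrix).
#' @param frame_period_s frame period in seconds.
#' @return an object of class \code{"spike_raster"}.
#' @export
build_raster <- function(binary, frame_period_s) {
  if (is.matrix(binary)) binary <- asplit(binary, 1)
  if (length(binary) == 0) stopf("cannot build a raster from zero ROIs")
  lens <- lengths(binary)
  if (length(unique(lens)) != 1) stopf("ragged binary series (lengths %s)",
                                       paste(unique(lens), collapse = ", "))
  m <- do.call(rbind, lapply(binary, as.integer))
  if (!all(m %in% c(0L, 1L))) stopf("raster entries must be 0/1")
  structure(list(spikes = m, frame_period_s = frame_period_s), class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("Binary raster: %d neurons x %d frames (%.3f s/frame), %d spikes\n",
              nrow(x$spikes), ncol(x$spikes), x$frame_period_s, sum(x$spikes)))
  invisible(x)
}

#' Run the full preprocessing chain on a trace set
#'
#' QC-selects ROIs, smooths, deconvolves and binarizes each surviving trace,
#' and stacks the result into a raster.
#'
#' @param traceset a \code{"trace_set"}.
#' @param psnr_min QC cutoff in dB.
#' @param window_s smoothing window (s).
#' @param tau_indicator_s indicator decay constant used for the AR(1)
#'   deconvolution factor \code{gamma = exp(-frame_period_s /
#'   tau_indicator_s)}; default 5.8 s, the GCaMP6s transient decay constant.
#' @param lam sparsity penalty; NULL for the per-trace noise estimate.
#' @param epsilon_floor binarization threshold floor.
#' @param strict strict PSNR comparison.
#' @return list with \code{raster}, \code{qc}, and the filtered
#'   \code{traceset}.
#' @export
preprocess_traces <- function(traceset, psnr_min = 10, window_s = 0.5,
                              tau_indicator_s = 5.8, lam = NULL,
                              epsilon_floor = 0.01, strict = TRUE) {
  sel <- select_rois(traceset, psnr_min = psnr_min, strict = strict,
                     epsilon_floor = epsilon_floor)
  ts <- sel$traceset
  dt <- ts$frame_period_s
  gamma <- exp(-dt / tau_indicator_s)
  psnr_kept <- sel$qc$psnr_db[sel$qc$passed]
  bin <- lapply(seq_len(nrow(ts$F_filtered)), function(i) {
    sm <- smooth_trace(ts$F_filtered[i, ], window_s = window_s,
                       frame_period_s = dt)
    s <- infer_spikes(sm, gamma = gamma, lam = lam)
    binarize_spikes(s, psnr_kept[i], epsilon_floor = epsilon_floor)
  })
  list(raster = build_raster(bin, dt), qc = sel$qc, traceset = ts)
}

#' Fit a single-exponential decay to a trace segment
#'
#' Nonlinear least squares of \code{a * exp(-t / tau)} over the windowed
#' segment, with \code{tau} bounded to \code{tau_bounds}. Initialization
#' comes from the log-linear closed form on the positive part of the
#' segment. Fits that end on a bound or fail to converge are flagged, not
#' silently returned.
#'
#' @param trace numeric trace.
#' @param window integer (start, end) frame indices into \code{trace}
#'   (1-based, inclusive), at least 3 samples.
#' @param frame_period_s frame period in seconds.
#' @param tau_bounds numeric (min, max) bounds for tau, seconds.
#' @return object of class \code{"decay_fit"}: \code{a}, \code{tau_s},
#'   \code{fit_rmse}, \code{window}, \code{at_bound}, \code{converged}.
#' @export
fit_decay <- function(trace, window, frame_period_s = 0.08,
                      tau_bounds = c(0.05, 60)) {
  w <- as.integer(window)
  if (length(w) != 2 || w[2] - w[1] + 1 < 3) stopf("window must span >= 3 samples")
  seg <- trace[w[1]:w[2]]
  tt <- (seq_along(seg) - 1) * frame_period_s
  if (seg[1] <= 0) stopf("trace must be positive at the window start")

  # log-linear start values (exact on noiseless exponentials)
  pos <- seg > 0
  if (sum(pos) >= 2) {
    fit0 <- stats::lm(log(seg[pos]) ~ tt[pos])
    a0 <- exp(unname(stats::coef(fit0)[1]))
    slope <- unname(stats::coef(fit0)[2])
    tau0 <- if (is.finite(slope) && slope < 0) -1 / slope else tau_bounds[2]
  } else {
    a0 <- seg[1]; tau0 <- 1
  }
  tau0 <- min(max(tau0, tau_bounds[1]), tau_bounds[2])
  a0 <- max(a0, 1e-9)

  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-t / tau),
                      data = data.frame(y = seg, t = tt),
                      start = list(a = a0, tau = tau0),
                      lower = c(0, tau_bounds[1]),
                      upper = c(Inf, tau_bounds[2]),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(a = a0, tau_s = tau0, fit_rmse = NA_real_,
                          window = w, at_bound = TRUE, converged = FALSE),
                     class = "decay_fit"))
  }
  cf <- stats::coef(fit)
  rmse <- sqrt(mean(stats::residuals(fit)^2))
  at_bound <- cf[["tau"]] <= tau_bounds[1] + 1e-9 ||
    cf[["tau"]] >= tau_bounds[2] - 1e-9
  structure(list(a = unname(cf[["a"]]), tau_s = unname(cf[["tau"]]),
                 fit_rmse = rmse, window = w, at_bound = at_bound,
                 converged = TRUE),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Exponential decay fit: a = %.4g, tau = %.4g s (rmse %.3g)%s\n",
              x$a, x$tau_s, x$fit_rmse,
              if (x$at_bound) " [at bound]" else ""))
  invisible(x)
}

# Detect decaying transients in a trace: local maxima above the robust
# threshold (median + k*MAD) followed by >= min_decay_s of non-increasing
# signal (5% tolerance). Returns data.frame(peak, end) of fit windows
# (peak to next rise or max_window_s, whichever first).
detect_transients <- function(trace, frame_period_s, k_mad = 3,
                              min_decay_s = 0.5, max_window_s = 2,
                              rise_tol = 0.05) {
  n <- length(trace)
  thr <- stats::median(trace) + k_mad * stats::mad(trace)
  if (!is.finite(thr)) return(data.frame(peak = integer(0), end = integer(0)))
  min_dec <- max(3L, round(min_decay_s / frame_period_s))
  max_win <- max(3L, round(max_window_s / frame_period_s))
  peaks <- which(trace > thr &
                   trace >= c(-Inf, trace[-n]) &
                   trace > c(trace[-1], -Inf))
  out <- data.frame(peak = integer(0), end = integer(0))
  for (p in peaks) {
    end <- p
    while (end < n && end - p < max_win &&
           trace[end + 1] <= trace[end] * (1 + rise_tol) + 1e-12) {
      end <- end + 1L
    }
    if (end - p + 1L >= min_dec) out <- rbind(out, data.frame(peak = p, end = end))
  }
  out
}

#' Decay time constants by stimulation condition
#'
#' Detects transient decays in each offsemble neuron's trace and fits the
#' exponential decay constant separately for three conditions:
#' \emph{spontaneous} (transients not overlapping any suppressing stimulus),
#' \emph{pre_onset} (the segment of a transient that ends at the onset of
#' the neuron's suppressing stimulus), and \emph{during} (the continued
#' decay inside the 2-s suppressing stimulus). A neuron's suppressing
#' stimuli are trials whose orientation matches an ensemble for which the
#' neuron is an offsemble member.
#'
#' @param traces matrix of neuropil-normalized (optionally smoothed) traces,
#'   neurons in rows, aligned to the raster frames.
#' @param schedule the stimulus schedule, or NULL for stimulus-free
#'   sessions (only the spontaneous condition is then populated).
#' @param membership N x E character membership matrix ("on"/"off"/"non").
#' @param ensemble_orientations_deg orientation of each ensemble (degrees).
#' @param frame_period_s frame period in seconds.
#' @param tau_bounds bounds for the decay fit (s).
#' @param neurons indices of neurons to analyze; defaults to all offsemble
#'   members (any ensemble).
#' @return object of class \code{"decay_by_condition"}: \code{fits}
#'   data.frame (neuron, condition, a, tau_s, rmse), \code{neuron_means} and
#'   \code{condition_means} (named means of tau per condition; conditions
#'   with no detected transients are reported empty/NA).
#' @export
decay_by_condition <- function(traces, schedule, membership,
                               ensemble_orientations_deg,
                               frame_period_s = 0.08,
                               tau_bounds = c(0.05, 60),
                               neurons = NULL) {
  if (is.null(neurons)) {
    neurons <- which(rowSums(membership == "off") > 0)
  }
  F_ <- ncol(traces)
  fits <- data.frame(neuron = integer(0), condition = character(0),
                     a = numeric(0), tau_s = numeric(0), rmse = numeric(0))
  trial_tab <- if (!is.null(schedule)) schedule$trials else
    data.frame(onset_frame = integer(0), duration_frames = integer(0),
               direction_deg = numeric(0))

  for (i in neurons) {
    tr <- traces[i, ]
    off_e <- which(membership[i, ] == "off")
    supp_orients <- ensemble_orientations_deg[off_e]
    supp_trials <- which(direction_to_orientation(trial_tab$direction_deg) %in%
                           supp_orients)
    supp_on <- trial_tab$onset_frame[supp_trials] + 1L
    supp_end <- pmin(supp_on + trial_tab$duration_frames[supp_trials] - 1L, F_)
    in_supp <- rep(FALSE, F_)
    for (j in seq_along(supp_on)) in_supp[supp_on[j]:supp_end[j]] <- TRUE

    trs <- detect_transients(tr, frame_period_s)
    add_fit <- function(win, cond) {
      if (win[2] - win[1] + 1 < 3 || tr[win[1]] <= 0) return(invisible())
      f <- tryCatch(fit_decay(tr, win, frame_period_s, tau_bounds),
                    error = function(e) NULL)
      if (!is.null(f) && f$converged && !f$at_bound) {
        fits[nrow(fits) + 1L, ] <<- list(i, cond, f$a, f$tau_s, f$fit_rmse)
      }
    }
    # spontaneous transients: windows clear of suppressing stimuli
    if (nrow(trs)) {
      for (k in seq_len(nrow(trs))) {
        if (!any(in_supp[trs$peak[k]:trs$end[k]])) {
          add_fit(c(trs$peak[k], trs$end[k]), "spontaneous")
        }
      }
    }
    # decays straddling a suppressing-stimulus onset: split at the onset
    for (j in seq_along(supp_on)) {
      on <- supp_on[j]
      if (on < 4 || !nrow(trs)) next
      prior <- trs$peak[trs$peak < on & trs$end >= on - 1L]
      if (!length(prior)) next
      pk <- max(prior)
      if (on - pk >= 3) add_fit(c(pk, on - 1L), "pre_onset")
      seg_end <- supp_end[j]
      # truncate the during-window at the next rise
      rise <- which(diff(tr[on:seg_end]) > 0.05 * abs(tr[on]) + 1e-12)
      if (length(rise)) seg_end <- on + rise[1] - 1L
      if (seg_end - on >= 2 && tr[on] > 0) add_fit(c(on, seg_end), "during")
    }
  }
  conds <- c("spontaneous", "pre_onset", "during")
  condition_means <- vapply(conds, function(cc) {
    v <- fits$tau_s[fits$condition == cc]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  neuron_means <- if (nrow(fits)) {
    stats::aggregate(tau_s ~ neuron + condition, data = fits, FUN = mean)
  } else data.frame(neuron = integer(0), condition = character(0),
                    tau_s = numeric(0))
  structure(list(fits = fits, neuron_means = neuron_means,
                 condition_means = condition_means),
            class = "decay_by_condition")
}

#' @export
print.decay_by_condition <- function(x, ...) {
  cat("Decay time constants by condition (cohort means, s):\n")
  for (cc in names(x$condition_means)) {
    n <- sum(x$fits$condition == cc)
    cat(sprintf("  %-12s %s  (n = %d transients)\n", cc,
                ifelse(is.na(x$condition_means[cc]), "empty",
                       sprintf("%.2f", x$condition_means[cc])), n))
  }
  invisible(x)
}
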