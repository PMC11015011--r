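#' Neuronal participation in ensembles
#'
#' The Ensemble Participation Index (EPI) measures how concentrated a
#' neuron's spiking is within the occurrence frames of an ensemble:
#' \deqn{EPI = 2 \cdot \frac{FiringRate_{ensemble}}{FiringRate_{ensemble} +
#' FiringRate_{outside}} - 1}
#' with firing rates computed as fraction of frames active during ensemble
#' occurrences vs outside them, i.e. a standard rate-modulation index.
#' +1 means exclusively active during ensemble events, -1 exclusively
#' active outside them, and 0 equal rates in both states regardless of how
#' much of the session the ensemble occupies. (A count-normalized variant,
#' 2 (spikes inside)/(total spikes) - 1, is available but is biased toward
#' -1 whenever occurrences cover a small fraction of the session.) Neurons
#' with significant positive EPI are onsemble members, significant negative
#' EPI offsemble members, the rest nonparticipants.
#'
#' @name participation
NULL

#' Ensemble Participation Index of one neuron
#'
#' @param neuron_spikes binary spike vector.
#' @param ensemble_signal binary ensemble occurrence vector, same length.
#' @param frame_mask optional logical vector restricting the computation
#'   (e.g. still vs running frames); default all frames.
#' @param method \code{"modulation"} (default): rate inside vs rate outside
#'   ensemble occurrences, \code{2 r_in / (r_in + r_out) - 1};
#'   \code{"count"}: \code{2 (spikes inside) / (total spikes) - 1};
#'   \code{"rate_ratio"}: the literal in-rate over whole-session rate,
#'   \code{2 r_in / r_total - 1}, clipped to \[-1, 1\].
#' @return the EPI in \[-1, 1\], or NA if the neuron has no spikes within
#'   the mask (undefined; such neurons are excluded from classification).
#' @export
epi <- function(neuron_spikes, ensemble_signal, frame_mask = NULL,
                method = c("modulation", "count", "rate_ratio")) {
  method <- match.arg(method)
  if (length(neuron_spikes) != length(ensemble_signal)) {
    stopf("spike and ensemble series differ in length")
  }
  mask <- if (is.null(frame_mask)) rep(TRUE, length(neuron_spikes)) else frame_mask
  sp <- neuron_spikes != 0 & mask
  ens <- ensemble_signal != 0 & mask
  total <- sum(sp)
  if (total == 0) return(NA_real_)
  if (method == "count") return(2 * sum(sp & ens) / total - 1)
  n_in <- sum(ens & mask); n_out <- sum(!ens & mask)
  if (n_in == 0 || (method == "modulation" && n_out == 0)) return(NA_real_)
  r_in <- sum(sp & ens) / n_in
  if (method == "rate_ratio") {
    r_tot <- total / sum(mask)
    return(max(-1, min(1, 2 * r_in / r_tot - 1)))
  }
  r_out <- sum(sp & !ens) / n_out
  if (r_in + r_out == 0) return(NA_real_)
  2 * r_in / (r_in + r_out) - 1
}

#' Classify onsemble / offsemble / nonparticipant neurons for one ensemble
#'
#' Per neuron, the fraction of frames active is computed within each
#' ensemble-occurrence epoch and within each complementary (inter-occurrence)
#' epoch; the two samples are compared by a two-sided Welch two-sample
#' t-test. Neurons with p < alpha and positive EPI are onsemble, with
#' p < alpha and negative EPI offsemble, all others nonparticipant.
#'
#' @param raster a \code{"spike_raster"} (or binary matrix, neurons in rows).
#' @param ensemble_signal binary occurrence vector with >= 2 occurrence
#'   epochs.
#' @param alpha significance level (default 0.05).
#' @param adjust p-value adjustment across neurons: \code{"none"} (default,
#'   per-neuron testing) or any \code{\link[stats]{p.adjust}} method.
#' @return a data.frame of class \code{"participation_table"}:
#'   \code{neuron_id}, \code{epi}, \code{firing_rate_ensemble},
#'   \code{firing_rate_total}, \code{p_value}, \code{class},
#'   \code{degenerate}.
#' @export
classify_participation <- function(raster, ensemble_signal, alpha = 0.05,
                                   adjust = "none") {
  X <- if (inherits(raster, "spike_raster")) raster$spikes else raster
  sig <- as.integer(ensemble_signal != 0)
  on_ep <- runs_of_ones(sig)
  off_ep <- runs_of_ones(1L - sig)
  if (nrow(on_ep) < 2) stopf("ensemble has %d occurrence epoch(s); need >= 2", nrow(on_ep))
  epoch_fracs <- function(spikes, ep) {
    vapply(seq_len(nrow(ep)),
           function(j) mean(spikes[ep$start[j]:ep$end[j]]), numeric(1))
  }
  N <- nrow(X)
  out <- data.frame(neuron_id = seq_len(N), epi = NA_real_,
                    firing_rate_ensemble = NA_real_,
                    firing_rate_total = NA_real_,
                    p_value = NA_real_, class = "nonparticipant",
                    degenerate = FALSE)
  ens_frames <- sig != 0
  for (i in seq_len(N)) {
    sp <- X[i, ]
    out$epi[i] <- epi(sp, sig)
    out$firing_rate_ensemble[i] <- if (any(ens_frames)) mean(sp[ens_frames]) else NA_real_
    out$firing_rate_total[i] <- mean(sp)
    a <- epoch_fracs(sp, on_ep)
    b <- epoch_fracs(sp, off_ep)
    tt <- tryCatch(stats::t.test(a, b), error = function(e) NULL)
    if (is.null(tt)) {
      out$p_value[i] <- 1
      out$degenerate[i] <- TRUE
    } else {
      out$p_value[i] <- tt$p.value
    }
  }
  padj <- stats::p.adjust(out$p_value, method = adjust)
  sig_i <- !is.na(out$epi) & !is.na(padj) & padj < alpha
  out$class[sig_i & out$epi > 0] <- "onsemble"
  out$class[sig_i & out$epi < 0] <- "offsemble"
  class(out) <- c("participation_table", "data.frame")
  out
}

#' @export
print.participation_table <- function(x, ...) {
  tab <- table(factor(x$class, levels = c("onsemble", "offsemble", "nonparticipant")))
  cat(sprintf("Participation: %d onsemble, %d offsemble, %d nonparticipant (of %d neurons)\n",
              tab["onsemble"], tab["offsemble"], tab["nonparticipant"], nrow(x)))
  invisible(x)
}

#' Participation table across all ensembles of a fit
#'
#' @param fit an \code{"ensemble_fit"}.
#' @param raster the raster the fit was computed on.
#' @param alpha significance level.
#' @param adjust p-value adjustment method.
#' @return data.frame with one block per ensemble (\code{ensemble_id}
#'   column) of \code{\link{classify_participation}} rows.
#' @export
participation_all <- function(fit, raster, alpha = 0.05, adjust = "none") {
  stopifnot(inherits(fit, "ensemble_fit"))
  blocks <- lapply(seq_along(fit$ensemble_ids), function(i) {
    tab <- classify_participation(raster, fit$signals[i, ], alpha = alpha,
                                  adjust = adjust)
    tab$ensemble_id <- fit$ensemble_ids[i]
    tab
  })
  out <- do.call(rbind, blocks)
  class(out) <- c("participation_table", "data.frame")
  out
}

#' Onset-aligned activity profiles by participation group
#'
#' Aligns the raster to the rising edges of an ensemble's occurrence signal
#' and reports, per relative frame, the mean fraction of active neurons in
#' the onsemble, offsemble and nonparticipant groups; plus the cumulative
#' fraction of onsemble members active at least once since onset, the peak
#' onsemble fraction and trough offsemble fraction with their latencies.
#'
#' @param raster a \code{"spike_raster"}.
#' @param ensemble_signal binary occurrence vector.
#' @param classes character vector per neuron in
#'   \{"onsemble","offsemble","nonparticipant"\}.
#' @param window_s numeric (before, after) window around onset, seconds
#'   (default c(-2, 2)).
#' @return object of class \code{"onset_profile"}: \code{time_s},
#'   \code{fraction} (matrix groups x time), \code{cumulative_onsemble},
#'   \code{peak}, \code{trough} (value + latency_s), \code{n_onsets}.
#' @export
onset_profile <- function(raster, ensemble_signal, classes,
                          window_s = c(-2, 2)) {
  X <- if (inherits(raster, "spike_raster")) raster$spikes else raster
  dt <- if (inherits(raster, "spike_raster")) raster$frame_period_s else 0.08
  F_ <- ncol(X)
  pre <- round(abs(window_s[1]) / dt); post <- round(window_s[2] / dt)
  starts <- runs_of_ones(ensemble_signal)$start
  starts <- starts[starts - pre >= 1 & starts + post <= F_]
  if (length(starts) == 0) stopf("no ensemble onset with a full window inside the session")
  rel <- (-pre):post
  groups <- c("onsemble", "offsemble", "nonparticipant")
  members <- lapply(groups, function(g) which(classes == g))
  names(members) <- groups
  frac <- matrix(NA_real_, 3, length(rel), dimnames = list(groups, NULL))
  for (g in groups) {
    idx <- members[[g]]
    if (!length(idx)) next
    acc <- matrix(0, length(starts), length(rel))
    for (s in seq_along(starts)) {
      acc[s, ] <- colMeans(X[idx, starts[s] + rel, drop = FALSE])
    }
    frac[g, ] <- colMeans(acc)
  }
  cum <- rep(NA_real_, length(rel))
  on_idx <- members$onsemble
  if (length(on_idx)) {
    post_rel <- which(rel >= 0)
    acc <- matrix(0, length(starts), length(post_rel))
    for (s in seq_along(starts)) {
      sub <- X[on_idx, starts[s] + rel[post_rel], drop = FALSE]
      seen <- (apply(sub, 1, cumsum) > 0)   # time x neurons
      acc[s, ] <- rowMeans(seen)
    }
    cum[post_rel] <- colMeans(acc)
  }
  post_sel <- rel >= 0
  peak <- trough <- list(value = NA_real_, latency_s = NA_real_)
  if (!all(is.na(frac["onsemble", ]))) {
    v <- frac["onsemble", post_sel]
    peak <- list(value = max(v), latency_s = rel[post_sel][which.max(v)] * dt)
  }
  if (!all(is.na(frac["offsemble", ]))) {
    v <- frac["offsemble", post_sel]
    trough <- list(value = min(v), latency_s = rel[post_sel][which.min(v)] * dt)
  }
  structure(list(time_s = rel * dt, fraction = frac,
                 cumulative_onsemble = cum, peak = peak, trough = trough,
                 n_onsets = length(starts)),
            class = "onset_profile")
}

#' @export
print.onset_profile <- function(x, ...) {
  cat(sprintf("Onset profile over %d onsets: onsemble peak %.3f at %.2f s; offsemble trough %.3f at %.2f s\n",
              x$n_onsets, x$peak$value, x$peak$latency_s,
              x$trough$value, x$trough$latency_s))
  invisible(x)
}

#' @export
plot.onset_profile <- function(x, ...) {
  cols <- c(onsemble = "firebrick", offsemble = "steelblue",
            nonparticipant = "gray50")
  graphics::matplot(x$time_s, t(x$fraction), type = "l", lty = 1,
                    col = cols, xlab = "time from ensemble onset (s)",
                    ylab = "fraction of active neurons", ...)
  graphics::abline(v = 0, lty = 2)
  graphics::legend("topleft", legend = rownames(x$fraction), col = cols,
                   lty = 1, bty = "n")
  invisible(x)
}

#' EPI split by locomotion state
#'
#' Partitions frames at \code{run_threshold} and computes every neuron's EPI
#' separately on the still and running partitions. The session is flagged
#' ineligible when running occupies less than \code{min_run_fraction} of the
#' frames; EPIs are still returned (NA where undefined).
#'
#' @param raster a \code{"spike_raster"}.
#' @param ensemble_signal binary occurrence vector.
#' @param speed_cm_s running-speed series aligned to frames.
#' @param run_threshold speed cutoff in cm/s (default 1).
#' @param min_run_fraction minimum fraction of running frames for an
#'   eligible session (default 0.05).
#' @return list with \code{epi_still}, \code{epi_running} (per neuron),
#'   \code{run_fraction}, \code{eligible}.
#' @export
epi_by_locomotion <- function(raster, ensemble_signal, speed_cm_s,
                              run_threshold = 1, min_run_fraction = 0.05) {
  X <- if (inherits(raster, "spike_raster")) raster$spikes else raster
  if (length(speed_cm_s) != ncol(X)) stopf("speed series not aligned to frames")
  running <- speed_cm_s > run_threshold
  rf <- mean(running)
  ep <- function(mask) {
    vapply(seq_len(nrow(X)),
           function(i) epi(X[i, ], ensemble_signal, frame_mask = mask),
           numeric(1))
  }
  list(epi_still = ep(!running),
       epi_running = if (any(running)) ep(running) else rep(NA_real_, nrow(X)),
       run_fraction = rf,
       eligible = rf >= min_run_fraction)
}

#' Fraction of frames with whisking above threshold
#'
#' @param whisking_energy nonnegative energy series.
#' @param threshold positive energy cutoff.
#' @return fraction of frames with energy > threshold.
#' @export
wakefulness_fraction <- function(whisking_energy, threshold) {
  if (threshold <= 0) stopf("threshold must be > 0")
  mean(whisking_energy > threshold)
}
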