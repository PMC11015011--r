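#' Stimulus-orientation decoding via informedness-optimal thresholds
#'
#' Each unit's trial responses are binarized at the ROC operating point that
#' maximizes informedness (hit rate minus false-alarm rate); four
#' predictors, one per orientation, vote per trial and the votes fill a 4x4
#' multiclass confusion matrix whose diagonal sum over total trials is the
#' decoding accuracy.
#'
#' @name decoding
NULL

#' Informedness-optimal response threshold for one unit
#'
#' Scans every distinct response value as a cutoff, in both inequality
#' directions (\code{">="} for responsive units, \code{"<="} for
#' anti-responsive units such as offsembles that go quiet on their
#' orientation), and returns the operating point maximizing informedness
#' = TPR - FPR. Ties prefer the \code{">="} direction, then the lower
#' threshold.
#'
#' @param responses numeric trial responses.
#' @param positive logical: is each trial of the predictor's assigned
#'   orientation.
#' @return object of class \code{"thresholded_predictor"}:
#'   \code{threshold}, \code{direction} (">=" or "<="),
#'   \code{informedness}, \code{flagged} (TRUE for constant responses).
#' @export
optimal_threshold <- function(responses, positive) {
  if (length(responses) != length(positive)) stopf("length mismatch")
  if (!any(positive) || all(positive)) {
    stopf("need at least one positive and one negative trial")
  }
  if (length(unique(responses)) == 1) {
    return(structure(list(threshold = responses[1], direction = ">=",
                          informedness = 0, flagged = TRUE),
                     class = "thresholded_predictor"))
  }
  cuts <- sort(unique(responses))
  npos <- sum(positive); nneg <- sum(!positive)
  best <- NULL
  for (dir in c(">=", "<=")) {
    for (c0 in cuts) {
      fires <- if (dir == ">=") responses >= c0 else responses <= c0
      J <- sum(fires & positive) / npos - sum(fires & !positive) / nneg
      cand <- list(threshold = c0, direction = dir, informedness = J)
      if (is.null(best) ||
          J > best$informedness + 1e-12 ||
          (abs(J - best$informedness) <= 1e-12 &&
           (dir == ">=" && best$direction == "<=" ||
            dir == best$direction && c0 < best$threshold))) {
        best <- cand
      }
    }
  }
  best$flagged <- FALSE
  structure(best, class = "thresholded_predictor")
}

#' @export
print.thresholded_predictor <- function(x, ...) {
  cat(sprintf("Predictor: fire when response %s %.4g (informedness %.3f)%s\n",
              x$direction, x$threshold, x$informedness,
              if (x$flagged) " [constant responses]" else ""))
  invisible(x)
}

# signed margin beyond the operating point (positive = fires)
predictor_margin <- function(pred, responses) {
  if (pred$direction == ">=") responses - pred$threshold
  else pred$threshold - responses
}

#' Predict the orientation of every trial from four thresholded predictors
#'
#' Each predictor fires when its inequality is met; the predicted
#' orientation is the one whose predictor fires. When zero or several fire,
#' the orientation with the largest signed margin beyond its threshold wins;
#' residual exact ties are broken by a seeded uniform draw.
#'
#' @param predictors named list of exactly 4
#'   \code{"thresholded_predictor"}s, names are the orientations (deg).
#' @param response_matrix 4 x n_trials matrix of responses, rows aligned
#'   with \code{predictors}.
#' @param seed integer seed for residual tie-breaks.
#' @return numeric vector of predicted orientations per trial.
#' @export
predict_trials <- function(predictors, response_matrix, seed = 1L) {
  if (length(predictors) != 4) stopf("exactly 4 predictors required")
  orients <- as.numeric(names(predictors))
  if (any(is.na(orients))) stopf("predictors must be named by orientation")
  n <- ncol(response_matrix)
  margins <- vapply(seq_len(4), function(i) {
    predictor_margin(predictors[[i]], response_matrix[i, ])
  }, numeric(n))
  margins <- matrix(margins, nrow = n)
  with_seed(substream_seed(seed, "decode-ties"), {
    vapply(seq_len(n), function(t) {
      m <- margins[t, ]
      top <- which(m >= max(m) - 1e-12)
      if (length(top) > 1) top <- sample(top, 1)
      orients[top]
    }, numeric(1))
  })
}

#' Multiclass confusion matrix and accuracy
#'
#' @param predictions predicted orientations per trial.
#' @param true_orientations true orientations, same length.
#' @param levels orientation levels (default the sorted unique true values).
#' @return object of class \code{"confusion_report"}: \code{matrix} (true x
#'   predicted counts), \code{accuracy} = diagonal sum / total trials,
#'   \code{n_trials}.
#' @export
confusion_and_accuracy <- function(predictions, true_orientations,
                                   levels = NULL) {
  if (length(predictions) != length(true_orientations)) {
    stopf("predictions and truths differ in length")
  }
  if (is.null(levels)) levels <- sort(unique(true_orientations))
  m <- table(factor(true_orientations, levels = levels),
             factor(predictions, levels = levels))
  m <- unclass(m)
  structure(list(matrix = m,
                 accuracy = sum(diag(m)) / sum(m),
                 n_trials = sum(m)),
            class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cat(sprintf("Confusion matrix (%d trials), accuracy = %.3f\n",
              x$n_trials, x$accuracy))
  print(x$matrix)
  invisible(x)
}

#' Averaged confusion matrices over random quadruples of tuned neurons
#'
#' Forms disjoint random sets of four neurons, one tuned to each
#' orientation, by shuffling each orientation pool and pairing by rank;
#' the number of sets is the smallest pool size. Per set, thresholds are
#' fit and the trials decoded; the count matrices are averaged.
#'
#' @param tuned_neurons data.frame with \code{neuron_id} and
#'   \code{theta_pref_deg} of significantly tuned neurons.
#' @param response_matrix neurons x trials response matrix (rows indexed by
#'   neuron_id).
#' @param true_orientations orientation of each trial (deg).
#' @param orientations the four orientations to decode (default 0,45,90,135).
#' @param seed integer seed.
#' @return object of class \code{"confusion_report"} with the averaged
#'   matrix, its accuracy, \code{n_sets_averaged}, and \code{set_accuracies}.
#' @export
neuron_set_confusions <- function(tuned_neurons, response_matrix,
                                  true_orientations,
                                  orientations = c(0, 45, 90, 135),
                                  seed = 1L) {
  pools <- lapply(orientations, function(o) {
    tuned_neurons$neuron_id[
      abs(wrap_orientation(tuned_neurons$theta_pref_deg - o)) < 22.5]
  })
  sizes <- lengths(pools)
  if (any(sizes == 0)) {
    stopf("no tuned neuron for orientation(s) %s deg",
          paste(orientations[sizes == 0], collapse = ", "))
  }
  n_sets <- min(sizes)
  with_seed(substream_seed(seed, "neuron-sets"), {
    pools <- lapply(pools, sample)
    mats <- vector("list", n_sets)
    accs <- numeric(n_sets)
    for (s in seq_len(n_sets)) {
      ids <- vapply(pools, `[`, numeric(1), s)
      preds <- lapply(seq_len(4), function(i) {
        optimal_threshold(response_matrix[ids[i], ],
                          true_orientations == orientations[i])
      })
      names(preds) <- orientations
      pr <- predict_trials(preds, response_matrix[ids, , drop = FALSE],
                           seed = seed + s)
      cr <- confusion_and_accuracy(pr, true_orientations, levels = orientations)
      mats[[s]] <- cr$matrix
      accs[s] <- cr$accuracy
    }
    avg <- Reduce(`+`, mats) / n_sets
    structure(list(matrix = avg, accuracy = sum(diag(avg)) / sum(avg),
                   n_trials = sum(mats[[1]]), n_sets_averaged = n_sets,
                   set_accuracies = accs),
              class = "confusion_report")
  })
}

#' Decode orientation from one predictor per orientation
#'
#' Convenience wrapper: fits the informedness-optimal threshold of each
#' unit's responses against its assigned orientation and decodes every
#' trial.
#'
#' @param response_matrix 4 x n_trials responses, rows named by assigned
#'   orientation (deg).
#' @param true_orientations trial orientations.
#' @param seed integer seed.
#' @return a \code{"confusion_report"}.
#' @export
decode_orientations <- function(response_matrix, true_orientations,
                                seed = 1L) {
  orients <- as.numeric(rownames(response_matrix))
  if (length(orients) != 4 || any(is.na(orients))) {
    stopf("response_matrix must have 4 rows named by orientation")
  }
  preds <- lapply(seq_len(4), function(i) {
    optimal_threshold(response_matrix[i, ], true_orientations == orients[i])
  })
  names(preds) <- orients
  pr <- predict_trials(preds, response_matrix, seed = seed)
  confusion_and_accuracy(pr, true_orientations, levels = sort(orients))
}

#' Offsemble-removal control
#'
#' Removes either the union of offsemble members of all orientation-tuned
#' ensembles, or an equal count of pure nonparticipant neurons with the
#' smallest participation (|EPI|), then re-runs ensemble detection on the
#' remaining population forcing the original number of significant
#' ensembles, and reports how many of the re-detected ensembles are
#' orientation tuned and their selectivity and tuning width.
#'
#' @param raster the full \code{"spike_raster"}.
#' @param fit the original \code{"ensemble_fit"}.
#' @param participation a \code{\link{participation_all}} table for the
#'   fit's ensembles.
#' @param schedule the stimulus schedule.
#' @param mode \code{"offsemble"} or \code{"nonparticipant"}.
#' @param alpha significance level for ensemble tuning.
#' @param n_surrogates,n_iter detection parameters for the re-run.
#' @param seed integer seed.
#' @return list with \code{mode}, \code{removed} (neuron ids),
#'   \code{n_removed}, \code{n_tuned_ensembles}, \code{mean_osi},
#'   \code{mean_sigma}, and the re-detected \code{ensemble_table}.
#' @export
removal_control <- function(raster, fit, participation, schedule,
                            mode = c("offsemble", "nonparticipant"),
                            alpha = 0.05, n_surrogates = 200, n_iter = 500,
                            seed = 1L) {
  mode <- match.arg(mode)
  etab <- ensemble_tuning(fit, schedule, alpha = alpha)
  sig <- etab[etab$significant, , drop = FALSE]
  if (nrow(sig) == 0) stopf("no orientation-encoding ensembles identified")
  # the orientation-encoding set: per stimulus orientation, the most
  # selective significant ensemble matching it
  orients <- sort(unique(direction_to_orientation(schedule$trials$direction_deg)))
  tuned_e <- unique(unlist(lapply(orients, function(o) {
    match_i <- which(abs(wrap_orientation(sig$theta_pref_deg - o)) < 22.5)
    if (!length(match_i)) return(NULL)
    sig$ensemble_id[match_i[which.max(sig$osi[match_i])]]
  })))
  sub <- participation[participation$ensemble_id %in% tuned_e, ]
  off_union <- unique(sub$neuron_id[sub$class == "offsemble"])
  is_member <- unique(sub$neuron_id[sub$class != "nonparticipant"])
  pure_non <- setdiff(unique(sub$neuron_id), is_member)
  if (length(off_union) == 0) stopf("no offsemble members in the orientation ensembles")
  if (length(pure_non) == 0) stopf("not enough nonparticipant neurons to match removal count")
  # matched removal count: as many neurons as both arms can supply
  n_remove <- min(length(off_union), length(pure_non))
  if (n_remove >= nrow(raster$spikes)) stopf("removal would exceed the population")

  strength_of <- function(ids) {
    vapply(ids, function(id) {
      v <- abs(sub$epi[sub$neuron_id == id])
      if (all(is.na(v))) 0 else max(v, na.rm = TRUE)
    }, numeric(1))
  }
  removed <- if (mode == "offsemble") {
    # strongest inactivation carriers first (most negative EPI)
    epi_min <- vapply(off_union, function(id) {
      v <- sub$epi[sub$neuron_id == id & sub$class == "offsemble"]
      min(v, na.rm = TRUE)
    }, numeric(1))
    off_union[order(epi_min)][seq_len(n_remove)]
  } else {
    # "least participant": nonparticipant in every orientation ensemble,
    # smallest |EPI| first
    pure_non[order(strength_of(pure_non))][seq_len(n_remove)]
  }

  keep <- setdiff(seq_len(nrow(raster$spikes)), removed)
  sub_raster <- raster
  sub_raster$spikes <- raster$spikes[keep, , drop = FALSE]
  refit <- detect_ensembles(sub_raster,
                            forced_k = length(fit$ensemble_ids),
                            n_surrogates = n_surrogates, n_iter = n_iter,
                            alpha = alpha, seed = seed)
  retab <- ensemble_tuning(refit, schedule, alpha = alpha)
  tuned <- retab[retab$significant, , drop = FALSE]
  list(mode = mode, removed = removed, n_removed = n_remove,
       n_tuned_ensembles = nrow(tuned),
       mean_osi = if (nrow(tuned)) mean(tuned$osi) else NA_real_,
       mean_sigma = if (nrow(tuned)) mean(tuned$sigma_deg) else NA_real_,
       ensemble_table = retab)
}
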