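#' Unsupervised ensemble detection from a binary raster
#'
#' Identifies statistically significant repeated population-activity
#' patterns (neuronal ensembles) without stimulus information: a
#' surrogate-tested functional network filters stray spikes from each
#' population vector, the remaining frames are clustered hierarchically on
#' Jaccard distance with Ward linkage, the number of clusters is chosen by
#' the maximum contrast index, and each cluster's within-similarity is
#' z-tested against random frame draws.
#'
#' @name ensembles
NULL

#' Functional network from coactivation statistics
#'
#' An edge connects neurons i and j when their observed coactivation count
#' (frames where both spike) is larger than expected under a null in which
#' every neuron's spike train is independently circularly shifted. The
#' one-sided exceedance p-value over \code{n_surrogates} shifts must fall
#' below \code{alpha}.
#'
#' @param raster a \code{"spike_raster"} (or plain binary matrix, neurons in
#'   rows).
#' @param n_surrogates number of circular-shift surrogates (default 1000).
#' @param alpha edge significance level (default 0.05).
#' @param bonferroni divide alpha by the number of neuron pairs.
#' @param seed integer seed.
#' @return object of class \code{"functional_network"}: \code{adjacency}
#'   (logical N x N, symmetric, no self-edges), \code{alpha},
#'   \code{n_surrogates}.
#' @export
functional_network <- function(raster, n_surrogates = 1000, alpha = 0.05,
                               bonferroni = FALSE, seed = 1L) {
  X <- if (inherits(raster, "spike_raster")) raster$spikes else raster
  if (!is.matrix(X) || length(X) == 0) stopf("raster must be a nonempty matrix")
  N <- nrow(X); F_ <- ncol(X)
  storage.mode(X) <- "double"
  obs <- tcrossprod(X)
  exceed <- matrix(0, N, N)
  rowi <- rep(seq_len(N), times = F_)
  colj <- rep(seq_len(F_), each = N)
  with_seed(substream_seed(seed, "network"), {
    for (b in seq_len(n_surrogates)) {
      s <- sample.int(F_, N, replace = TRUE) - 1L
      cidx <- ((colj - 1L + s[rowi]) %% F_) + 1L
      Xs <- matrix(X[(cidx - 1L) * N + rowi], N, F_)
      exceed <- exceed + (tcrossprod(Xs) >= obs)
    }
  })
  pmat <- exceed / n_surrogates
  a <- if (bonferroni) alpha / (N * (N - 1) / 2) else alpha
  adj <- (pmat < a) & (obs > 0)
  adj <- adj & t(adj)
  diag(adj) <- FALSE
  structure(list(adjacency = adj, alpha = alpha, n_surrogates = n_surrogates),
            class = "functional_network")
}

#' @export
print.functional_network <- function(x, ...) {
  n <- nrow(x$adjacency)
  cat(sprintf("Functional network: %d neurons, %d edges (alpha = %g, %d surrogates)\n",
              n, sum(x$adjacency) / 2, x$alpha, x$n_surrogates))
  invisible(x)
}

#' Remove spikes of nonconnected neurons from each population vector
#'
#' Within every frame, a spike survives only if its neuron has at least one
#' functional-network neighbor that is also active in that frame.
#'
#' @param raster a \code{"spike_raster"}.
#' @param network a \code{"functional_network"} over the same neurons.
#' @return the filtered \code{"spike_raster"}.
#' @export
filter_raster <- function(raster, network) {
  X <- raster$spikes
  A <- network$adjacency
  if (nrow(A) != nrow(X)) stopf("network and raster cover different neuron counts")
  storage.mode(X) <- "double"
  neigh_active <- (A * 1) %*% X
  out <- raster
  out$spikes <- matrix(as.integer(X > 0 & neigh_active > 0), nrow(X), ncol(X))
  out
}

#' Jaccard similarity of two binary population vectors
#'
#' Intersection over union; defined as 0 when both vectors are empty.
#'
#' @param frame_u,frame_v binary vectors of equal length.
#' @return similarity in \[0, 1\].
#' @export
jaccard_similarity <- function(frame_u, frame_v) {
  if (length(frame_u) != length(frame_v)) stopf("vectors differ in length")
  u <- frame_u != 0; v <- frame_v != 0
  un <- sum(u | v)
  if (un == 0) return(0)
  sum(u & v) / un
}

# All-pairs Jaccard similarity between the columns of a binary matrix.
frame_similarity <- function(M) {
  storage.mode(M) <- "double"
  int <- crossprod(M)
  s <- colSums(M)
  un <- outer(s, s, "+") - int
  J <- ifelse(un > 0, int / un, 0)
  diag(J) <- 1
  J
}

#' Hierarchical clustering of population vectors
#'
#' Excludes all-zero frames, computes 1 - Jaccard distance between the
#' remaining column vectors, agglomerates with Ward linkage
#' (\code{hclust} \code{"ward.D2"} on the precomputed dissimilarity) and
#' cuts the tree at every candidate k.
#'
#' @param filtered_raster a \code{"spike_raster"} (typically network-filtered).
#' @param k_min,k_max candidate cluster-count range.
#' @return list with \code{frames} (indices of the clustered, nonempty
#'   frames), \code{similarity} (Jaccard matrix over those frames),
#'   \code{hclust}, and \code{labels_by_k} (matrix, one column per k).
#' @export
cluster_frames <- function(filtered_raster, k_min = 2, k_max = 10) {
  X <- filtered_raster$spikes
  nonempty <- which(colSums(X) > 0)
  m <- length(nonempty)
  if (m < k_max) stopf("only %d nonempty frames for k_max = %d clusters", m, k_max)
  M <- X[, nonempty, drop = FALSE]
  J <- frame_similarity(M)
  hc <- stats::hclust(stats::as.dist(1 - J), method = "ward.D2")
  ks <- k_min:k_max
  labels <- vapply(ks, function(k) stats::cutree(hc, k), integer(m))
  colnames(labels) <- as.character(ks)
  list(frames = nonempty, similarity = J, hclust = hc, labels_by_k = labels)
}

#' Cluster-separation contrast index
#'
#' Mean over clusters of (mean within-cluster similarity - mean similarity
#' of cluster members to non-members). Singleton clusters contribute a
#' within-similarity of 1 by convention.
#'
#' @param similarity_matrix symmetric similarity matrix over clustered
#'   frames.
#' @param labels integer cluster labels (>= 2 distinct values).
#' @return scalar contrast index.
#' @export
contrast_index <- function(similarity_matrix, labels) {
  cl <- sort(unique(labels))
  if (length(cl) < 2) stopf("contrast index undefined for a single cluster")
  per <- vapply(cl, function(c0) {
    idx <- which(labels == c0)
    within <- if (length(idx) < 2) 1 else {
      sub <- similarity_matrix[idx, idx]
      mean(sub[upper.tri(sub)])
    }
    between <- mean(similarity_matrix[idx, -idx, drop = FALSE])
    within - between
  }, numeric(1))
  mean(per)
}

#' Choose the number of clusters by maximum contrast index
#'
#' @param contrast_by_k named numeric vector (names are candidate k).
#' @return the k maximizing the index; ties resolved toward the smallest k.
#' @export
select_k <- function(contrast_by_k) {
  if (length(contrast_by_k) == 0) stopf("no candidate k supplied")
  ks <- as.integer(names(contrast_by_k))
  best <- max(contrast_by_k)
  min(ks[contrast_by_k >= best - 1e-12])
}

#' z-test of cluster coherence against random frame draws
#'
#' For a cluster of m frames, the observed mean pairwise Jaccard similarity
#' is compared with the distribution of the same statistic over
#' \code{n_iter} uniform draws (without replacement) of m clustered frames:
#' z = (s_obs - mean_null) / sd_null, one-sided p = P(Z >= z). Clusters of
#' size 1 have undefined within-similarity and are excluded with a warning.
#'
#' @param frame_labels integer labels over the clustered frames.
#' @param similarity the Jaccard similarity matrix over the same frames (as
#'   returned by \code{\link{cluster_frames}}).
#' @param n_iter null draws (default 1000).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed.
#' @return list with \code{cluster_pvalues}, \code{z_stats}, \code{s_obs}
#'   (named per cluster) and \code{ensemble_ids} (clusters with p < alpha).
#' @export
test_ensembles <- function(frame_labels, similarity, n_iter = 1000,
                           alpha = 0.05, seed = 1L) {
  m_all <- length(frame_labels)
  cl <- sort(unique(frame_labels))
  sizes <- vapply(cl, function(c0) sum(frame_labels == c0), integer(1))
  if (any(sizes == 1)) {
    warning("excluding singleton cluster(s) from the ensemble test: ",
            paste(cl[sizes == 1], collapse = ", "))
  }
  mean_pair <- function(idx) {
    sub <- similarity[idx, idx]
    mean(sub[upper.tri(sub)])
  }
  pvals <- zs <- sobs <- stats::setNames(rep(NA_real_, length(cl)), cl)
  with_seed(substream_seed(seed, "ensemble-test"), {
    for (ci in seq_along(cl)) {
      m <- sizes[ci]
      if (m < 2) next
      idx <- which(frame_labels == cl[ci])
      s_obs <- mean_pair(idx)
      null <- vapply(seq_len(n_iter),
                     function(b) mean_pair(sample.int(m_all, m)), numeric(1))
      mu <- mean(null); sdv <- stats::sd(null)
      if (is.na(sdv) || sdv == 0) {
        p <- (1 + sum(null >= s_obs)) / (n_iter + 1)
        z <- NA_real_
      } else {
        z <- (s_obs - mu) / sdv
        p <- stats::pnorm(z, lower.tail = FALSE)
      }
      pvals[ci] <- p; zs[ci] <- z; sobs[ci] <- s_obs
    }
  })
  list(cluster_pvalues = pvals, z_stats = zs, s_obs = sobs,
       ensemble_ids = cl[!is.na(pvals) & pvals < alpha])
}

#' Per-ensemble binary occurrence signals
#'
#' \code{signal_e[f] = 1} iff frame f carries cluster label e and e is a
#' significant ensemble. Signals are pairwise disjoint because every frame
#' has at most one label.
#'
#' @param frame_labels labels over the clustered frames.
#' @param frames session-frame indices of the clustered frames.
#' @param ensemble_ids significant cluster ids.
#' @param session_frames total frame count.
#' @return binary matrix, one row per ensemble (rownames are cluster ids).
#' @export
ensemble_signals <- function(frame_labels, frames, ensemble_ids,
                             session_frames) {
  sig <- matrix(0L, length(ensemble_ids), session_frames,
                dimnames = list(as.character(ensemble_ids), NULL))
  for (i in seq_along(ensemble_ids)) {
    sig[i, frames[frame_labels == ensemble_ids[i]]] <- 1L
  }
  sig
}

#' Detect neuronal ensembles in a binary raster
#'
#' The full unsupervised chain: functional-network extraction, per-frame
#' spike filtering, Jaccard/Ward clustering of population vectors, cluster
#' count by maximum contrast index (or a forced k), and a z-test of each
#' cluster against random frame draws.
#'
#' @param raster a \code{"spike_raster"}.
#' @param k_min,k_max candidate cluster-count range (default 2..10).
#' @param n_surrogates circular-shift surrogates for the network null.
#' @param n_iter null draws for the cluster z-test.
#' @param alpha significance level used for both the network edges and the
#'   cluster test (default 0.05).
#' @param forced_k re-cluster at this fixed k, bypassing contrast-index
#'   selection (used by the removal control).
#' @param seed integer seed.
#' @return an object of class \code{"ensemble_fit"} with the network, the
#'   filtered raster, clustered frame indices and labels, contrast curve,
#'   selected k, per-cluster z/p, \code{ensemble_ids}, and the per-ensemble
#'   binary \code{signals}.
#' @export
detect_ensembles <- function(raster, k_min = 2, k_max = 10,
                             n_surrogates = 1000, n_iter = 1000,
                             alpha = 0.05, forced_k = NULL, seed = 1L) {
  net <- functional_network(raster, n_surrogates = n_surrogates,
                            alpha = alpha, seed = seed)
  filt <- filter_raster(raster, net)
  if (!is.null(forced_k)) {
    cl <- cluster_frames(filt, k_min = forced_k, k_max = forced_k)
    contrast <- stats::setNames(
      contrast_index(cl$similarity, cl$labels_by_k[, 1]), forced_k)
    k_star <- forced_k
  } else {
    cl <- cluster_frames(filt, k_min = k_min, k_max = k_max)
    contrast <- apply(cl$labels_by_k, 2, contrast_index,
                      similarity_matrix = cl$similarity)
    k_star <- select_k(contrast)
  }
  labels <- cl$labels_by_k[, as.character(k_star)]
  tst <- test_ensembles(labels, cl$similarity, n_iter = n_iter,
                        alpha = alpha, seed = seed)
  signals <- ensemble_signals(labels, cl$frames, tst$ensemble_ids,
                              ncol(raster$spikes))
  structure(list(
    network = net,
    filtered_raster = filt,
    frames = cl$frames,
    frame_labels = labels,
    contrast_by_k = contrast,
    n_clusters = k_star,
    cluster_pvalues = tst$cluster_pvalues,
    z_stats = tst$z_stats,
    s_obs = tst$s_obs,
    ensemble_ids = tst$ensemble_ids,
    signals = signals,
    alpha = alpha,
    frame_period_s = raster$frame_period_s,
    n_neurons = nrow(raster$spikes),
    session_frames = ncol(raster$spikes)
  ), class = "ensemble_fit")
}

#' @export
print.ensemble_fit <- function(x, ...) {
  cat(sprintf("Ensemble fit: %d neurons x %d frames; %d clustered frames\n",
              x$n_neurons, x$session_frames, length(x$frames)))
  cat(sprintf("  k* = %d clusters, %d significant ensembles (alpha = %g)\n",
              x$n_clusters, length(x$ensemble_ids), x$alpha))
  invisible(x)
}

#' @export
summary.ensemble_fit <- function(object, ...) {
  cl <- as.integer(names(object$cluster_pvalues))
  tab <- data.frame(
    cluster = cl,
    n_frames = vapply(cl, function(c0) sum(object$frame_labels == c0), integer(1)),
    within_similarity = unname(object$s_obs),
    z = unname(object$z_stats),
    p_value = unname(object$cluster_pvalues),
    ensemble = cl %in% object$ensemble_ids
  )
  structure(list(table = tab, n_clusters = object$n_clusters,
                 contrast_by_k = object$contrast_by_k),
            class = "summary.ensemble_fit")
}

#' @export
print.summary.ensemble_fit <- function(x, ...) {
  cat("Cluster significance (z-test against random frame draws):\n")
  print(x$table, row.names = FALSE, digits = 3)
  cat("\nContrast index by k:\n")
  print(round(x$contrast_by_k, 3))
  invisible(x)
}

#' Diagnostic plot of an ensemble fit
#'
#' Left: raster with clustered frames reordered by cluster label (dots are
#' spikes). Right: contrast index across candidate k with the selected k
#' marked.
#'
#' @param x an \code{"ensemble_fit"}.
#' @param ... ignored.
#' @export
plot.ensemble_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  ord <- x$frames[order(x$frame_labels)]
  M <- x$filtered_raster$spikes[, ord, drop = FALSE]
  graphics::image(t(M), col = c("white", "black"), axes = FALSE,
                  xlab = "clustered frames (sorted by cluster)",
                  ylab = "neurons", main = "filtered raster")
  graphics::box()
  ks <- as.integer(names(x$contrast_by_k))
  graphics::plot(ks, x$contrast_by_k, type = "b", xlab = "k",
                 ylab = "contrast index", main = "cluster-count selection")
  graphics::abline(v = x$n_clusters, lty = 2)
  invisible(x)
}
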