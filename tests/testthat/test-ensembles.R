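test_that("functional network links true coactivation and calibrates on noise", {
  # identical spike trains: coactivation far above the circular-shift null
  set.seed(2)
  train <- integer(1000); train[sample(1000, 50)] <- 1L
  X <- rbind(train, train, rbinom(1000, 1, 0.05))
  net <- functional_network(X, n_surrogates = 500, seed = 2)
  expect_true(net$adjacency[1, 2])
  expect_false(any(diag(net$adjacency)))
  expect_identical(net$adjacency, t(net$adjacency))

  # independent neurons: edge rate near alpha over pairs
  set.seed(3)
  Xn <- matrix(rbinom(30 * 3000, 1, 0.05), 30, 3000)
  netn <- functional_network(Xn, n_surrogates = 500, seed = 3)
  rate <- sum(netn$adjacency) / (30 * 29)
  se <- sqrt(0.05 * 0.95 / choose(30, 2))
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("per-frame filtering keeps spikes only with an active network neighbor", {
  X <- matrix(0L, 3, 4)
  X[, 1] <- c(1L, 1L, 1L)   # frame with actives {A,B,C}
  X[1, 2] <- 1L             # A alone
  net <- structure(list(adjacency = matrix(c(FALSE, TRUE, FALSE,
                                             TRUE, FALSE, FALSE,
                                             FALSE, FALSE, FALSE), 3, 3)),
                   class = "functional_network")
  ra <- structure(list(spikes = X, frame_period_s = 0.08), class = "spike_raster")
  filt <- filter_raster(ra, net)
  expect_identical(filt$spikes[, 1], c(1L, 1L, 0L))  # C dropped, A-B kept
  expect_identical(sum(filt$spikes[, 2]), 0L)        # lone spike dropped
  # edgeless network empties everything
  net0 <- structure(list(adjacency = matrix(FALSE, 3, 3)),
                    class = "functional_network")
  expect_identical(sum(filter_raster(ra, net0)$spikes), 0L)
  # fully connected network keeps frames with >= 2 active neurons intact
  net1 <- structure(list(adjacency = matrix(TRUE, 3, 3) & !diag(3) > 0),
                    class = "functional_network")
  expect_identical(filter_raster(ra, net1)$spikes[, 1], X[, 1])
})

test_that("Jaccard similarity matches hand values and the all-pairs oracle", {
  expect_equal(jaccard_similarity(c(1, 1, 0, 1), c(1, 1, 0, 1)), 1)
  expect_equal(jaccard_similarity(c(1, 0, 0), c(0, 1, 0)), 0)
  expect_equal(jaccard_similarity(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 / 3)
  expect_equal(jaccard_similarity(c(0, 0), c(0, 0)), 0)
  # frame_similarity vs elementwise oracle on random <= 8-frame toys
  set.seed(4)
  for (rep in 1:10) {
    M <- matrix(rbinom(6 * 8, 1, 0.4), 6, 8)
    J <- onsembles:::frame_similarity(M)
    for (i in 1:8) for (j in 1:8) {
      expect_equal(J[i, j],
                   if (i == j) 1 else jaccard_similarity(M[, i], M[, j]))
    }
  }
})

test_that("clustering separates planted repeated patterns exactly", {
  pat1 <- c(rep(1L, 5), rep(0L, 5))
  pat2 <- c(rep(0L, 5), rep(1L, 5))
  X <- cbind(matrix(pat1, 10, 6), matrix(pat2, 10, 6))
  ra <- structure(list(spikes = X, frame_period_s = 0.08), class = "spike_raster")
  cl <- cluster_frames(ra, k_min = 2, k_max = 4)
  lab <- cl$labels_by_k[, "2"]
  expect_identical(length(unique(lab[1:6])), 1L)
  expect_identical(length(unique(lab[7:12])), 1L)
  expect_false(lab[1] == lab[7])
  expect_equal(contrast_index(cl$similarity, lab), 1)
  expect_error(cluster_frames(ra, k_min = 2, k_max = 20), "nonempty frames")
})

test_that("the contrast index is near zero for random labels and relabel-invariant", {
  set.seed(5)
  M <- matrix(rbinom(20 * 500, 1, 0.2), 20, 500)
  J <- onsembles:::frame_similarity(M)
  lab <- sample(1:4, 500, replace = TRUE)
  expect_lt(abs(contrast_index(J, lab)), 0.05)
  relab <- c(3L, 1L, 4L, 2L)[lab]
  expect_equal(contrast_index(J, lab), contrast_index(J, relab))
  expect_error(contrast_index(J, rep(1L, 500)), "single cluster")
})

test_that("cluster-count selection takes the argmax with smallest-k ties", {
  expect_identical(select_k(c(`2` = 0.3, `3` = 0.9, `4` = 0.5)), 3L)
  expect_identical(select_k(c(`2` = 0.9, `5` = 0.9)), 2L)
})

test_that("the coherence z-test flags planted clusters and calibrates on noise", {
  pat <- c(rep(1L, 6), rep(0L, 14))
  set.seed(6)
  Xr <- matrix(rbinom(20 * 80, 1, 0.15), 20, 80)
  X <- cbind(matrix(pat, 20, 20), Xr)
  J <- onsembles:::frame_similarity(X)
  lab <- c(rep(1L, 20), rep(2L, 80))
  tst <- test_ensembles(lab, J, n_iter = 1000, seed = 6)
  expect_lt(tst$cluster_pvalues["1"], 1e-3)
  expect_true(1L %in% tst$ensemble_ids)

  # false-positive rate of a random "cluster" of i.i.d. frames is near alpha
  set.seed(7)
  hits <- vapply(1:300, function(b) {
    Xi <- matrix(rbinom(15 * 60, 1, 0.2), 15, 60)
    Ji <- onsembles:::frame_similarity(Xi)
    labi <- c(rep(1L, 12), rep(2L, 48))
    p <- test_ensembles(labi, Ji, n_iter = 300, seed = b)$cluster_pvalues["1"]
    p < 0.05
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.05), 0.04)   # ~3 SE at 300 repeats
  expect_gt(mean(hits), 0.002)

  # singleton clusters are excluded with a warning
  expect_warning(test_ensembles(c(1L, 2L, 2L, 2L), J[1:4, 1:4], n_iter = 50,
                                seed = 1), "singleton")
})

test_that("ensemble occurrence signals are disjoint and conserve frame counts", {
  lab <- c(1L, 1L, 2L, 3L, 2L)
  frames <- c(2L, 4L, 5L, 7L, 9L)
  sig <- ensemble_signals(lab, frames, ensemble_ids = c(1L, 2L), session_frames = 10)
  expect_true(all(colSums(sig) <= 1))
  expect_identical(sum(sig), 4L)                 # cluster 3 not significant
  expect_identical(which(sig["1", ] == 1L), c(2L, 4L))
})

test_that("detection recovers planted orientation ensembles irrespective of neuron order", {
  sess <- planted_session(21, regime = "clean", n_neurons = 150, duration_s = 240,
                          reps_min = 5)
  fit <- detect_ensembles(sess$ra, n_surrogates = 300, n_iter = 400, seed = 21)
  set.seed(21)
  perm <- sample(nrow(sess$ra$spikes))
  ra_p <- sess$ra; ra_p$spikes <- sess$ra$spikes[perm, ]
  fit_p <- detect_ensembles(ra_p, n_surrogates = 300, n_iter = 400, seed = 22)
  truth <- truth_frame_labels(sess$sch)
  ari <- mclust::adjustedRandIndex
  expect_gte(ari(fit$frame_labels, truth[fit$frames]), 0.8)
  expect_gte(ari(fit_p$frame_labels, truth[fit_p$frames]), 0.8)
})
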