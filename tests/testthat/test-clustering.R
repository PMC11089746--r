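test_that("min-max normalization maps features into [0,1] with recorded extrema", {
  X <- cbind(a = c(1, 5, 10), b = c(0, 0.5, 1))
  out <- min_max_normalize(X)
  expect_equal(unname(out[, "a"]), c(0, 4 / 9, 1))
  expect_equal(unname(out[, "b"]), c(0, 0.5, 1))  # already [0,1]: unchanged
  expect_equal(unname(attr(out, "min")), c(1, 0))
  expect_equal(unname(attr(out, "max")), c(10, 1))
})

test_that("constant features normalize to zero with a warning and stay inert", {
  X <- cbind(c(1, 2, 3), c(3, 3, 3))
  expect_warning(out <- min_max_normalize(X), "constant")
  expect_equal(unname(out[, 2]), c(0, 0, 0))
  # downstream measures unaffected: the tied feature resolves identically
  expect_equal(inversions(out[1, ], out[2, ])$count,
               inversions(X[1, 1], X[2, 1])$count)
})

test_that("centroid initialization is reproducible and respects its mode", {
  X <- two_blob_data()
  Xn <- min_max_normalize(X)
  set.seed(3)
  c1 <- init_centroids(Xn, 4, "forgy")
  set.seed(3)
  c2 <- init_centroids(Xn, 4, "forgy")
  expect_identical(c1, c2)
  # m == k forgy: centroids are a permutation of the objects
  set.seed(8)
  call <- init_centroids(Xn, nrow(Xn), "forgy")
  expect_equal(dim(call), dim(Xn))
  expect_true(all(call[order(call[, 1]), ] == Xn[order(Xn[, 1]), ]))
  expect_error(init_centroids(Xn, nrow(Xn) + 1, "forgy"), "m <=")
})

test_that("uniform initialization fills the unit cube with mean 1/2", {
  set.seed(12)
  X <- matrix(stats::runif(20), 10, 2)
  draws <- init_centroids(X, 5000, "uniform")
  expect_true(all(draws >= 0 & draws <= 1))
  se <- sqrt(1 / 12 / length(draws))
  expect_lt(abs(mean(draws) - 0.5), 3 * se)
})

test_that("assignment matches an exhaustive per-object measure table", {
  set.seed(21)
  X <- matrix(stats::runif(12 * 4), 12, 4)
  centroids <- matrix(stats::runif(3 * 4), 3, 4)
  for (msr in c("euclidean", "inv", "rieca")) {
    labels <- assign_clusters(X, centroids, measure = msr)
    fun <- switch(msr, euclidean = euclidean_dist,
                  inv = inv_measure, rieca = rieca_measure)
    for (i in seq_len(nrow(X))) {
      vals <- vapply(seq_len(3), function(j) fun(X[i, ], centroids[j, ]), 1)
      expect_equal(vals[labels[i]], min(vals))
    }
  }
})

test_that("measure ties fall back to Euclidean distance, then cluster index", {
  # both centroids rank features identically to the object -> rieca = 0;
  # the Euclidean-nearer centroid must win
  obj <- c(0.2, 0.5, 0.9)
  far <- c(0.1, 0.4, 0.8)
  near <- c(0.19, 0.49, 0.89)
  labels <- assign_clusters(rbind(obj), rbind(far, near), measure = "rieca")
  expect_equal(labels, 2L)
  # exact full tie: lowest cluster index
  labels <- assign_clusters(rbind(obj), rbind(obj, obj), measure = "euclidean")
  expect_equal(labels, 1L)
})

test_that("an object equal to a centroid is assigned to it under any measure", {
  set.seed(4)
  centroids <- matrix(stats::runif(12), 3, 4)
  for (msr in c("euclidean", "inv", "rieca")) {
    expect_equal(assign_clusters(rbind(centroids[2, ]), centroids,
                                 measure = msr), 2L)
  }
})

test_that("centroid update takes cluster means and re-seeds empty clusters", {
  X <- rbind(c(0, 0), c(1, 1), c(4, 4))
  cent <- update_centroids(X, c(1L, 1L, 2L), 2L)
  expect_equal(cent[1, ], c(0.5, 0.5))
  expect_equal(cent[2, ], c(4, 4))  # singleton: centroid is the object
  set.seed(1)
  cent3 <- update_centroids(X, c(1L, 1L, 2L), 3L)
  expect_equal(attr(cent3, "reseeded"), 3L)
  # re-seeded centroid is one of the data objects
  expect_true(any(apply(X, 1, function(r) all(r == cent3[3, ]))))
})

test_that("the fitted partition covers every object exactly once", {
  X <- two_blob_data()
  for (msr in c("inv", "rieca", "euclidean")) {
    fit <- inv_cluster(X, 2, measure = msr, seed = 5, n_restarts = 3)
    expect_length(fit$labels, nrow(X))
    expect_true(all(fit$labels %in% 1:2))
    expect_true(fit$converged)
  }
})

test_that("m = 1 collapses to the global mean in at most two passes", {
  X <- two_blob_data()
  fit <- inv_cluster(X, 1, measure = "euclidean", seed = 2, n_restarts = 1)
  expect_true(all(fit$labels == 1L))
  expect_lte(fit$n_iter, 2L)
  Xn <- min_max_normalize(X)
  expect_equal(unname(fit$centroids[1, ]), unname(colMeans(Xn)))
})

test_that("identical config and seed give identical results", {
  X <- two_blob_data(seed = 6)
  f1 <- inv_cluster(X, 3, measure = "rieca", seed = 77)
  f2 <- inv_cluster(X, 3, measure = "rieca", seed = 77)
  expect_identical(f1[c("labels", "centroids", "objective", "n_iter")],
                   f2[c("labels", "centroids", "objective", "n_iter")])
})

test_that("the Euclidean objective is non-increasing across iterations", {
  set.seed(14)
  X <- matrix(stats::runif(80 * 3), 80, 3)
  centroids <- init_centroids(X, 4, "forgy")
  prev <- Inf
  for (iter in 1:25) {
    labels <- assign_clusters(X, centroids, measure = "euclidean")
    obj <- sum(vapply(seq_len(nrow(X)), function(i)
      euclidean_dist(X[i, ], centroids[labels[i], ]), 1))
    expect_lte(obj, prev + 1e-12)
    prev <- obj
    centroids <- update_centroids(X, labels, 4)
  }
})

test_that("inv and rieca fits terminate and their assignments are stable", {
  ds <- simulate_dataset(80, 5, 3, omega = 0.2, seed = 10)
  for (msr in c("inv", "rieca")) {
    fit <- inv_cluster(ds$data, 3, measure = msr, seed = 10, n_restarts = 2)
    expect_lte(fit$n_iter, 100L)
    if (fit$converged) {
      Xn <- min_max_normalize(ds$data)
      again <- assign_clusters(Xn, fit$centroids, measure = msr)
      expect_identical(again, fit$labels)
    }
  }
})

test_that("assignment is equivariant under object reordering when measures are distinct", {
  set.seed(33)
  X <- matrix(stats::rnorm(40 * 4), 40, 4)
  centroids <- matrix(stats::rnorm(3 * 4), 3, 4)
  perm <- sample.int(40)
  l1 <- assign_clusters(X, centroids, measure = "rieca")
  l2 <- assign_clusters(X[perm, ], centroids, measure = "rieca")
  expect_identical(l2, l1[perm])
})

test_that("with the Euclidean measure the framework reproduces Lloyd k-means", {
  aris <- vapply(1:10, framework_matches_kmeans, 1)
  expect_true(all(aris == 1))
})

test_that("well-separated data is recovered almost perfectly by RIECA", {
  aris <- vapply(1:20, function(s) {
    ds <- simulate_dataset(100, 4, 2, omega = 0.001, seed = 1000 + s)
    fit <- inv_cluster(ds$data, 2, measure = "rieca", seed = s,
                       n_restarts = 5)
    adjusted_rand_index(ds$labels, fit$labels)
  }, 1)
  expect_gt(mean(aris), 0.9)
})

test_that("the vectorized engine agrees with the scalar measures", {
  set.seed(55)
  X <- matrix(stats::rnorm(10 * 6), 10, 6)
  C <- matrix(stats::rnorm(3 * 6), 3, 6)
  w <- stats::runif(6, 0.5, 2)
  pw <- invclust:::pair_weights_for(w, 6)
  mm <- invclust:::measure_matrix(X, C, "inv", pw)
  for (i in 1:10) for (j in 1:3) {
    expect_equal(mm$M[i, j], inv_measure(X[i, ], C[j, ], priorities = w))
  }
  mm2 <- invclust:::measure_matrix(X, C, "rieca")
  for (i in 1:10) for (j in 1:3) {
    expect_equal(mm2$M[i, j], rieca_measure(X[i, ], C[j, ]))
  }
})

test_that("invalid configurations are rejected", {
  X <- two_blob_data()
  expect_error(inv_cluster(X, 0), "between 1")
  expect_error(inv_cluster(X, nrow(X) + 1), "between 1")
  expect_error(inv_cluster(X, 2, max_iter = 0), "at least 1")
})
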