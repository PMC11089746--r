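#' Min-max normalize the columns of a feature matrix
#'
#' Rescales each feature to `[0, 1]` by `(x - min) / (max - min)`, computed
#' over all objects. A constant feature, for which the formula is 0/0, is
#' mapped to all zeros with a warning: the feature then contributes nothing
#' to Euclidean distances, and its rank ties resolve by the tie order.
#'
#' @param X Numeric matrix or data frame, one row per object, one column
#'   per feature.
#' @return Numeric matrix of the same shape with attributes `"min"` and
#'   `"max"` holding the per-feature extrema used (for inverse mapping).
#' @examples
#' min_max_normalize(cbind(a = c(1, 5, 10)))[, 1]  # 0 4/9 1
#' @export
min_max_normalize <- function(X) {
  X <- check_matrix(X)
  mins <- apply(X, 2L, min)
  maxs <- apply(X, 2L, max)
  rng <- maxs - mins
  const <- rng == 0
  if (any(const)) {
    warning("constant feature(s) ",
            paste(which(const), collapse = ", "),
            " mapped to 0", call. = FALSE)
    rng[const] <- 1
  }
  out <- sweep(sweep(X, 2L, mins, `-`), 2L, rng, `/`)
  out[, const] <- 0
  attr(out, "min") <- mins
  attr(out, "max") <- maxs
  out
}

#' Initialize cluster centroids
#'
#' `"forgy"` draws `m` distinct data objects as centroids; `"uniform"`
#' samples each coordinate uniformly in `[0, 1]` (the feature space after
#' min-max normalization). Uses the current RNG state.
#'
#' @param X Numeric matrix of (normalized) data, objects in rows.
#' @param m Number of clusters.
#' @param init One of `"forgy"`, `"uniform"`.
#' @return `m x ncol(X)` numeric matrix of centroids.
#' @export
init_centroids <- function(X, m, init = c("forgy", "uniform")) {
  X <- check_matrix(X)
  init <- match.arg(init)
  if (m < 1L) stop("'m' must be at least 1", call. = FALSE)
  if (init == "forgy") {
    if (m > nrow(X)) {
      stop("forgy initialization needs m <= number of objects (",
           m, " > ", nrow(X), ")", call. = FALSE)
    }
    X[sample.int(nrow(X), m), , drop = FALSE]
  } else {
    matrix(stats::runif(m * ncol(X)), nrow = m, ncol = ncol(X))
  }
}

#' Assign objects to the nearest centroid under a measure
#'
#' Each object goes to the centroid minimizing the chosen measure.
#' Exact measure ties are broken by raw Euclidean distance, then by lowest
#' cluster index — relevant mainly for the RIECA measure, which is zero for
#' every centroid ranked identically to the object.
#'
#' @inheritParams init_centroids
#' @param centroids Numeric matrix of centroids, one per row.
#' @param measure One of `"rieca"`, `"inv"`, `"euclidean"`.
#' @param priorities Positive per-feature weights (default all 1).
#' @param tie_order Permutation breaking exact value ties in rankings.
#' @return Integer vector of cluster labels in `1:nrow(centroids)`.
#' @export
assign_clusters <- function(X, centroids, measure = "rieca",
                            priorities = NULL,
                            tie_order = seq_len(ncol(X))) {
  X <- check_matrix(X)
  centroids <- check_matrix(centroids, "centroids")
  if (ncol(centroids) != ncol(X)) {
    stop("'centroids' must have the same number of features as 'X'",
         call. = FALSE)
  }
  measure <- check_measure(measure)
  pw <- pair_weights_for(priorities, ncol(X))
  mm <- measure_matrix(X, centroids, measure, pw, tie_order)
  argmin_with_ties(mm$M, mm$D)
}

# priorities -> per-feature-pair products, NULL when uniform
pair_weights_for <- function(priorities, n) {
  if (is.null(priorities)) return(NULL)
  priorities <- check_priorities(priorities, n)
  if (all(priorities == 1)) return(NULL)
  pr <- feature_pairs(n)
  priorities[pr[, 1L]] * priorities[pr[, 2L]]
}

# row-wise argmin of M; ties by D, then lowest column index
argmin_with_ties <- function(M, D) {
  first <- max.col(-M, ties.method = "first")
  rowmin <- M[cbind(seq_len(nrow(M)), first)]
  D2 <- D
  D2[M > rowmin] <- Inf
  max.col(-D2, ties.method = "first")
}

#' Recompute centroids as cluster means
#'
#' Each centroid becomes the coordinate-wise mean of the objects assigned
#' to it. A cluster left empty by the assignment is re-seeded with a
#' uniformly drawn data object (using the current RNG state) and recorded
#' in the `"reseeded"` attribute.
#'
#' @inheritParams init_centroids
#' @param labels Integer vector of cluster labels in `1:m`.
#' @return `m x ncol(X)` matrix of centroids, with attribute `"reseeded"`
#'   listing the indices of re-seeded (empty) clusters.
#' @export
update_centroids <- function(X, labels, m) {
  X <- check_matrix(X)
  cent <- matrix(NA_real_, nrow = m, ncol = ncol(X))
  reseeded <- integer(0)
  for (j in seq_len(m)) {
    members <- labels == j
    if (any(members)) {
      cent[j, ] <- colMeans(X[members, , drop = FALSE])
    } else {
      cent[j, ] <- X[sample.int(nrow(X), 1L), ]
      reseeded <- c(reseeded, j)
    }
  }
  attr(cent, "reseeded") <- reseeded
  cent
}

#' Inversion-based partitioning clustering (ICA / RIECA framework)
#'
#' The k-means-style framework: min-max normalize, initialize `m`
#' centroids, then alternate (a) assigning each object to the centroid
#' minimizing the chosen measure and (b) moving each centroid to the mean
#' of its cluster, until no label changes or `max_iter` passes are reached.
#' `measure = "inv"` gives ICA (assignment by inversion count),
#' `measure = "rieca"` gives RIECA (inversion count times Euclidean
#' distance), and `measure = "euclidean"` reduces the framework to Lloyd's
#' k-means. Several random restarts are run and the solution with the
#' lowest objective (sum of each object's measure to its centroid) is
#' returned.
#'
#' @param X Numeric matrix or data frame, one object per row.
#' @param m Number of clusters, at most `nrow(X)`.
#' @param measure Assignment measure: `"rieca"` (default), `"inv"`, or
#'   `"euclidean"`.
#' @param priorities Optional positive per-feature weights for the
#'   inversion count (default: all equal).
#' @param tie_order Permutation of feature indices breaking exact rank
#'   ties; default ascending index.
#' @param max_iter Maximum assignment passes per restart (default 100).
#' @param n_restarts Number of random restarts (default 10).
#' @param init Centroid initialization, `"forgy"` (random data objects,
#'   default) or `"uniform"` (uniform in the normalized feature space).
#' @param seed Optional integer; restart r uses seed `seed + r - 1`, making
#'   the whole fit reproducible.
#' @param normalize Apply [min_max_normalize()] first (default `TRUE`).
#'   Set `FALSE` if `X` is already normalized.
#' @return Object of class `"inv_cluster"`: list with `labels` (integer
#'   vector), `centroids` (in normalized coordinates), `n_iter`,
#'   `converged`, `objective`, `measure`, `m`, `degenerate` (TRUE if the
#'   best restart ended with an empty, re-seeded cluster), and
#'   `restart_objectives`.
#' @examples
#' set.seed(1)
#' X <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 4), 30))
#' fit <- inv_cluster(X, m = 2, measure = "rieca", seed = 7)
#' table(fit$labels)
#' @export
inv_cluster <- function(X, m, measure = c("rieca", "inv", "euclidean"),
                        priorities = NULL, tie_order = NULL,
                        max_iter = 100L, n_restarts = 10L,
                        init = c("forgy", "uniform"), seed = NULL,
                        normalize = TRUE) {
  X <- check_matrix(X)
  measure <- match.arg(measure)
  init <- match.arg(init)
  k <- nrow(X)
  if (m < 1L || m > k) {
    stop("'m' must be between 1 and the number of objects (", k, ")",
         call. = FALSE)
  }
  if (max_iter < 1L || n_restarts < 1L) {
    stop("'max_iter' and 'n_restarts' must be at least 1", call. = FALSE)
  }
  tie_order <- if (is.null(tie_order)) seq_len(ncol(X))
               else check_permutation(tie_order, ncol(X), "tie_order")
  Xn <- if (normalize) min_max_normalize(X) else X
  pw <- pair_weights_for(priorities, ncol(X))
  # object pair-signs are fixed across the whole fit
  SX <- if (measure != "euclidean") pair_sign_matrix(Xn, tie_order) else NULL

  best <- NULL
  objectives <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    if (!is.null(seed)) set.seed(as.integer(seed) + r - 1L)
    run <- cluster_once(Xn, m, measure, pw, tie_order, SX, max_iter, init)
    objectives[r] <- run$objective
    if (is.null(best) || run$objective < best$objective) best <- run
  }
  structure(
    list(labels = best$labels, centroids = best$centroids,
         n_iter = best$n_iter, converged = best$converged,
         objective = best$objective, measure = measure, m = m,
         degenerate = best$degenerate, restart_objectives = objectives,
         normalized = normalize, seed = seed),
    class = "inv_cluster"
  )
}

# single restart of the assign/update loop on pre-normalized data
cluster_once <- function(Xn, m, measure, pw, tie_order, SX, max_iter, init) {
  centroids <- init_centroids(Xn, m, init)
  labels <- NULL
  converged <- FALSE
  n_iter <- 0L
  M <- NULL
  for (iter in seq_len(max_iter)) {
    n_iter <- iter
    mm <- measure_matrix(Xn, centroids, measure, pw, tie_order, SX = SX)
    M <- mm$M
    new_labels <- argmin_with_ties(M, mm$D)
    if (identical(new_labels, labels)) {
      converged <- TRUE
      break
    }
    labels <- new_labels
    centroids <- update_centroids(Xn, labels, m)
  }
  list(labels = labels,
       centroids = centroids,
       n_iter = n_iter,
       converged = converged,
       degenerate = any(tabulate(labels, m) == 0L),
       objective = sum(M[cbind(seq_len(nrow(Xn)), labels)]))
}

#' @export
print.inv_cluster <- function(x, ...) {
  algo <- switch(x$measure, inv = "ICA", rieca = "RIECA",
                 euclidean = "k-means (framework)")
  cat(algo, "clustering:", x$m, "clusters,", length(x$labels), "objects\n")
  cat("  objective:", format(x$objective), "  iterations:", x$n_iter,
      if (x$converged) "(converged)" else "(iteration cap reached)", "\n")
  cat("  cluster sizes:", paste(tabulate(x$labels, x$m), collapse = ", "),
      "\n")
  if (x$degenerate) cat("  note: an empty cluster was re-seeded\n")
  invisible(x)
}

#' Inversion-Based Clustering Algorithm (ICA)
#'
#' Convenience wrapper: [inv_cluster()] with `measure = "inv"`.
#' @inheritParams inv_cluster
#' @param ... Passed on to [inv_cluster()].
#' @return See [inv_cluster()].
#' @export
ica <- function(X, m, ...) inv_cluster(X, m, measure = "inv", ...)

#' Regulator Inversion Euclidean distance Clustering Algorithm (RIECA)
#'
#' Convenience wrapper: [inv_cluster()] with `measure = "rieca"`.
#' @inheritParams ica
#' @return See [inv_cluster()].
#' @export
rieca <- function(X, m, ...) inv_cluster(X, m, measure = "rieca", ...)
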