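#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement of two labelings of the same objects,
#' computed from the contingency table by the Hubert-Arabie formula:
#' identical partitions (up to relabeling) score 1, independent random
#' partitions score about 0, and worse-than-chance agreement is negative.
#'
#' @param labels_a,labels_b Vectors of cluster labels of equal length
#'   (any atomic type; compared as factors).
#' @return Numeric ARI in `[-1, 1]`.
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1: same partition
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  n <- length(labels_a)
  if (n < 2L) stop("need at least two objects", call. = FALSE)
  if (anyNA(labels_a) || anyNA(labels_b)) {
    stop("labels must not contain NA", call. = FALSE)
  }
  tab <- table(labels_a, labels_b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions degenerate
  (sum_ij - expected) / (max_index - expected)
}

#' One-way analysis of variance across groups
#'
#' Classical fixed-effects one-way ANOVA of several samples: the ratio of
#' between-group to within-group mean squares on `(g - 1, N - g)` degrees
#' of freedom, via [stats::oneway.test()] with equal variances assumed.
#' A degenerate case with zero within-group variance but unequal group
#' means is reported as `F = Inf`, `p = 0` and flagged.
#'
#' @param groups Named list of numeric vectors, one per group; at least
#'   two groups of at least two values each.
#' @return List with `statistic` (F), `p_value`, `df_between`,
#'   `df_within`, and `degenerate`.
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4)))$statistic  # 1.5
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("'groups' must be a list of at least two numeric vectors",
         call. = FALSE)
  }
  if (any(vapply(groups, length, 1L) < 2L)) {
    stop("each group needs at least two values", call. = FALSE)
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  df1 <- nlevels(g) - 1L
  df2 <- length(values) - nlevels(g)
  within_ss <- sum(tapply(values, g, function(v) sum((v - mean(v))^2)))
  if (within_ss == 0) {
    means <- tapply(values, g, mean)
    if (max(means) > min(means)) {
      return(list(statistic = Inf, p_value = 0, df_between = df1,
                  df_within = df2, degenerate = TRUE))
    }
    return(list(statistic = 0, p_value = 1, df_between = df1,
                df_within = df2, degenerate = TRUE))
  }
  fit <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(statistic = unname(fit$statistic), p_value = unname(fit$p.value),
       df_between = df1, df_within = df2, degenerate = FALSE)
}

# ---- baseline algorithm adapters -------------------------------------------
# Thin wrappers returning integer labels, all run on the same min-max
# normalized data with the true cluster count, mirroring the known-m
# benchmark protocol.

baseline_algorithms <- c("ica", "rieca", "kmeans", "em", "hierarchical",
                         "kmedoids")

# Run Mclust without attaching mclust: its internals re-evaluate helper
# calls in the caller's frame, so give it a frame whose parent is the
# mclust namespace.
mclust_em <- function(Xn, m, modelNames = NULL) {
  env <- new.env(parent = asNamespace("mclust"))
  env$.data <- Xn
  env$.G <- m
  env$.models <- modelNames
  eval(quote(Mclust(.data, G = .G, modelNames = .models, verbose = FALSE)),
       env)
}

run_algorithm <- function(name, Xn, m, seed, n_restarts = 10L,
                          max_iter = 100L, linkage = "complete") {
  switch(name,
    ica = inv_cluster(Xn, m, measure = "inv", n_restarts = n_restarts,
                      max_iter = max_iter, seed = seed,
                      normalize = FALSE)$labels,
    rieca = inv_cluster(Xn, m, measure = "rieca", n_restarts = n_restarts,
                        max_iter = max_iter, seed = seed,
                        normalize = FALSE)$labels,
    kmeans = {
      set.seed(seed)
      stats::kmeans(Xn, centers = m, nstart = n_restarts,
                    iter.max = max_iter)$cluster
    },
    em = {
      set.seed(seed)
      fit <- mclust_em(Xn, m)
      # model-based EM can fail on degenerate draws; fall back to
      # spherical equal-volume components
      if (length(fit$classification) == 0L) {
        fit <- mclust_em(Xn, m, modelNames = "EII")
      }
      fit$classification
    },
    hierarchical = {
      stats::cutree(stats::hclust(stats::dist(Xn), method = linkage), k = m)
    },
    kmedoids = cluster::pam(Xn, k = m, cluster.only = TRUE),
    stop("unknown algorithm '", name, "'", call. = FALSE)
  )
}

#' Benchmark clustering algorithms on overlap-calibrated mixtures
#'
#' Reproduces the simulation-study design: for each combination of dataset
#' family and average pairwise overlap, generate `reps` labeled datasets
#' with [simulate_dataset()], min-max normalize, run every requested
#' algorithm with the true cluster count, and score each run by adjusted
#' Rand index against the generating labels. Per cell, algorithms are also
#' compared by one-way ANOVA over their per-replicate ARI values.
#'
#' Replicate r of a cell uses seed `seed + r`, so all algorithms within a
#' cell see identical datasets and the whole report is reproducible.
#'
#' @param families Which benchmark shapes to run: `1` is 200 points x 6
#'   features x 5 clusters, `2` is 500 points x 7 features x 10 clusters.
#' @param omegas Numeric vector of target average pairwise overlaps.
#' @param algorithms Subset of `c("ica", "rieca", "kmeans", "em",
#'   "hierarchical", "kmedoids")`.
#' @param reps Replicate datasets per cell (default 100).
#' @param seed Base integer seed of the replicate seed ladder.
#' @param n_restarts Random restarts for ICA/RIECA and k-means.
#' @param linkage Agglomeration method for the hierarchical baseline.
#' @return Object of class `"benchmark_report"`: list with `ari` (long
#'   data frame: family, omega, algorithm, replicate, seed, ari),
#'   `summary` (mean, sd, reps per cell and algorithm), `anova` (F and p
#'   per cell), `best` (highest mean-ARI algorithm per cell), and the
#'   configuration used.
#' @examples
#' \donttest{
#' rep <- run_benchmark(families = 1, omegas = 0.05,
#'                      algorithms = c("kmeans", "rieca"),
#'                      reps = 5, seed = 1)
#' rep$summary
#' }
#' @export
run_benchmark <- function(families = 1L,
                          omegas = c(0.4, 0.3, 0.2, 0.05, 0.001),
                          algorithms = baseline_algorithms,
                          reps = 100L, seed = 1L, n_restarts = 10L,
                          linkage = "complete") {
  algorithms <- match.arg(algorithms, baseline_algorithms,
                          several.ok = TRUE)
  stopifnot(all(families %in% c(1L, 2L)), reps >= 1L)
  shapes <- list(`1` = list(n = 200L, d = 6L, m = 5L),
                 `2` = list(n = 500L, d = 7L, m = 10L))
  rows <- list()
  for (fam in families) {
    shape <- shapes[[as.character(fam)]]
    for (omega in omegas) {
      for (r in seq_len(reps)) {
        rep_seed <- as.integer(seed) + r
        ds <- simulate_dataset(shape$n, shape$d, shape$m, omega,
                               seed = rep_seed)
        Xn <- suppressWarnings(min_max_normalize(ds$data))
        for (alg in algorithms) {
          pred <- run_algorithm(alg, Xn, shape$m, seed = rep_seed,
                                n_restarts = n_restarts, linkage = linkage)
          rows[[length(rows) + 1L]] <- data.frame(
            family = fam, omega = omega, algorithm = alg, replicate = r,
            seed = rep_seed,
            ari = adjusted_rand_index(ds$labels, pred))
        }
      }
    }
  }
  ari <- do.call(rbind, rows)
  summary_df <- stats::aggregate(ari ~ family + omega + algorithm,
                                 data = ari,
                                 FUN = function(v) c(mean = mean(v),
                                                     sd = stats::sd(v),
                                                     reps = length(v)))
  summary_df <- cbind(summary_df[, c("family", "omega", "algorithm")],
                      as.data.frame(summary_df$ari))
  anova_rows <- list()
  best_rows <- list()
  for (fam in unique(ari$family)) {
    for (omega in unique(ari$omega)) {
      cell <- ari[ari$family == fam & ari$omega == omega, ]
      if (nrow(cell) == 0L) next
      cs <- summary_df[summary_df$family == fam & summary_df$omega == omega, ]
      best_rows[[length(best_rows) + 1L]] <- data.frame(
        family = fam, omega = omega,
        best_algorithm = cs$algorithm[which.max(cs$mean)],
        mean_ari = max(cs$mean))
      if (length(unique(cell$algorithm)) >= 2L && reps >= 2L) {
        groups <- split(cell$ari, cell$algorithm)
        aov_res <- one_way_anova(groups)
        anova_rows[[length(anova_rows) + 1L]] <- data.frame(
          family = fam, omega = omega, F = aov_res$statistic,
          p = aov_res$p_value)
      }
    }
  }
  structure(
    list(ari = ari, summary = summary_df,
         anova = if (length(anova_rows)) do.call(rbind, anova_rows),
         best = do.call(rbind, best_rows),
         config = list(families = families, omegas = omegas,
                       algorithms = algorithms, reps = reps, seed = seed,
                       n_restarts = n_restarts, linkage = linkage)),
    class = "benchmark_report"
  )
}

#' @export
print.benchmark_report <- function(x, digits = 3L, ...) {
  cat("Clustering benchmark:", x$config$reps, "replicates per cell\n\n")
  s <- x$summary
  s$mean <- round(s$mean, digits)
  s$sd <- round(s$sd, digits)
  print(s, row.names = FALSE)
  cat("\nBest algorithm per cell:\n")
  b <- x$best
  b$mean_ari <- round(b$mean_ari, digits)
  print(b, row.names = FALSE)
  invisible(x)
}
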