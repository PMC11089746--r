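#' Pairwise overlap of two spherical Gaussian components
#'
#' For two equally weighted components `N(mu_i, sigma^2 I)` and
#' `N(mu_j, sigma^2 I)`, the overlap is the total probability mass each
#' misclassifies into the other under the Bayes (nearest-mean) rule:
#' `omega_ij = 2 * Phi(-d / (2 * sigma))` with `d = ||mu_i - mu_j||`.
#' Coincident means give 1; infinitely separated means give 0.
#'
#' @param mu_i,mu_j Numeric mean vectors of equal length.
#' @param sigma Shared spherical standard deviation, `> 0`.
#' @return Overlap probability in `(0, 1]`.
#' @examples
#' pairwise_overlap(0, 2, 1)  # 2 * pnorm(-1) ~ 0.3173
#' @export
pairwise_overlap <- function(mu_i, mu_j, sigma) {
  mu_i <- check_object_vector(mu_i, "mu_i")
  mu_j <- check_object_vector(mu_j, "mu_j")
  if (length(mu_i) != length(mu_j)) {
    stop("'mu_i' and 'mu_j' must have the same dimension", call. = FALSE)
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("'sigma' must be a single positive number", call. = FALSE)
  }
  2 * stats::pnorm(-sqrt(sum((mu_i - mu_j)^2)) / (2 * sigma))
}

# mean of omega_ij over all m(m-1)/2 component pairs
average_overlap <- function(means, sigma) {
  d <- as.vector(stats::dist(means))
  mean(2 * stats::pnorm(-d / (2 * sigma)))
}

#' Calibrate a Gaussian mixture to a target average pairwise overlap
#'
#' Draws `m` component means uniformly in the unit hypercube, then rescales
#' them about their centroid by a single factor, found by monotone
#' bisection, so that the mean of all pairwise overlaps hits
#' `omega_target`. All components share a spherical covariance
#' `sigma^2 I` and, by default, equal mixing weights. Uses the current RNG
#' state for the mean draw.
#'
#' @param m Number of components, `>= 2`.
#' @param d Dimension.
#' @param omega_target Target average pairwise overlap, in `(0, 0.5)`;
#'   small values give well-separated clusters, large values heavily
#'   overlapping ones.
#' @param sigma Shared spherical standard deviation (default 0.1; the
#'   separation scale adapts to it, so it only sets the units).
#' @param tol Calibration tolerance on the achieved overlap (default 1e-4).
#' @return Object of class `"mixture_spec"`: list with `means` (`m x d`
#'   matrix), `sigma`, `weights`, `omega_target`, `omega_achieved`.
#' @examples
#' set.seed(42)
#' spec <- calibrate_mixture(5, 6, omega_target = 0.05)
#' spec$omega_achieved
#' @export
calibrate_mixture <- function(m, d, omega_target, sigma = 0.1, tol = 1e-4) {
  if (m < 2L) stop("'m' must be at least 2", call. = FALSE)
  if (!is.numeric(omega_target) || omega_target <= 0 || omega_target >= 0.5) {
    stop("'omega_target' must lie in (0, 0.5)", call. = FALSE)
  }
  means0 <- matrix(stats::runif(m * d), nrow = m, ncol = d)
  center <- colMeans(means0)
  dev <- sweep(means0, 2L, center, `-`)
  scaled_means <- function(s) sweep(dev * s, 2L, center, `+`)
  f <- function(s) average_overlap(scaled_means(s), sigma)

  # f is continuous and strictly decreasing in s, with f(0) = 1
  lo <- 0
  hi <- 1
  expansions <- 0L
  while (f(hi) > omega_target) {
    hi <- hi * 2
    expansions <- expansions + 1L
    if (expansions > 60L) {
      stop("overlap calibration failed to bracket target ", omega_target,
           " (overlap at scale ", hi, " is ", signif(f(hi), 4L), ")",
           call. = FALSE)
    }
  }
  s <- hi
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm - omega_target) <= tol / 2) {
      s <- mid
      break
    }
    if (fm > omega_target) lo <- mid else hi <- mid
    s <- mid
  }
  means <- scaled_means(s)
  achieved <- average_overlap(means, sigma)
  if (abs(achieved - omega_target) > tol) {
    stop("overlap calibration did not converge: achieved ",
         signif(achieved, 6L), " for target ", omega_target, call. = FALSE)
  }
  structure(
    list(means = means, sigma = sigma, weights = rep(1 / m, m),
         omega_target = omega_target, omega_achieved = achieved),
    class = "mixture_spec"
  )
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat("Gaussian mixture spec:", nrow(x$means), "spherical components in",
      ncol(x$means), "dimensions\n")
  cat("  sigma:", x$sigma, "  average pairwise overlap:",
      signif(x$omega_achieved, 6L), "(target", x$omega_target, ")\n")
  invisible(x)
}

#' Sample a labeled dataset from a mixture specification
#'
#' Draws each point's component from the mixing weights, then its
#' coordinates from that component's spherical Gaussian.
#'
#' @param spec A `"mixture_spec"` from [calibrate_mixture()].
#' @param n Number of points, at least the number of components.
#' @param seed Optional integer seed for reproducibility.
#' @return Object of class `"sim_dataset"`: list with `data` (`n x d`
#'   matrix), `labels` (generating component of each point), `spec`,
#'   `seed`.
#' @export
sample_mixture <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "mixture_spec"))
  m <- nrow(spec$means)
  if (n < m) stop("'n' must be at least the number of components",
                  call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  comp <- sample.int(m, n, replace = TRUE, prob = spec$weights)
  d <- ncol(spec$means)
  X <- spec$means[comp, , drop = FALSE] +
    matrix(stats::rnorm(n * d, sd = spec$sigma), nrow = n, ncol = d)
  colnames(X) <- paste0("f", seq_len(d))
  structure(list(data = X, labels = comp, spec = spec, seed = seed),
            class = "sim_dataset")
}

#' Monte-Carlo check of the pairwise overlap formula
#'
#' Estimates the overlap of two spherical components by simulation: draws
#' points from each component in equal numbers, classifies every point to
#' the nearer of the two means (the Bayes rule for equal weights and a
#' shared spherical covariance), and returns twice the misclassification
#' rate — the Monte-Carlo counterpart of [pairwise_overlap()].
#'
#' @inheritParams pairwise_overlap
#' @param n Total number of simulated points.
#' @return List with `omega_hat` (estimate), `se` (its standard error),
#'   and `n`.
#' @export
mc_pairwise_overlap <- function(mu_i, mu_j, sigma, n = 1e5) {
  mu_i <- check_object_vector(mu_i, "mu_i")
  mu_j <- check_object_vector(mu_j, "mu_j")
  err <- c(pair_errors(mu_i, mu_j, sigma, ceiling(n / 2)),
           pair_errors(mu_j, mu_i, sigma, floor(n / 2)))
  p <- mean(err)
  list(omega_hat = 2 * p, se = 2 * sqrt(p * (1 - p) / length(err)),
       n = length(err))
}

#' Monte-Carlo check of a calibrated mixture's average overlap
#'
#' Validates a [calibrate_mixture()] specification by simulation: points
#' are allocated equally over the component pairs, drawn from one of the
#' pair's two components, and classified to the nearer of the two means.
#' Twice the pooled misclassification rate estimates the average pairwise
#' overlap the specification was calibrated to.
#'
#' @param spec A `"mixture_spec"`.
#' @param n Total number of simulated points (split across pairs).
#' @param seed Optional integer seed.
#' @return List with `omega_hat`, its standard error `se`, the analytic
#'   `omega_analytic`, and `n`.
#' @export
mc_average_overlap <- function(spec, n = 1e5, seed = NULL) {
  stopifnot(inherits(spec, "mixture_spec"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  m <- nrow(spec$means)
  pairs <- feature_pairs(m)  # index pairs i < j over components
  P <- nrow(pairs)
  n_per <- diff(round(seq(0, n, length.out = P + 1L)))
  est <- var_sum <- 0
  for (p in seq_len(P)) {
    mu_a <- spec$means[pairs[p, 1L], ]
    mu_b <- spec$means[pairs[p, 2L], ]
    err <- c(pair_errors(mu_a, mu_b, spec$sigma, ceiling(n_per[p] / 2)),
             pair_errors(mu_b, mu_a, spec$sigma, floor(n_per[p] / 2)))
    rate <- mean(err)
    est <- est + 2 * rate / P
    var_sum <- var_sum + 4 * rate * (1 - rate) / length(err) / P^2
  }
  list(omega_hat = est, se = sqrt(var_sum),
       omega_analytic = average_overlap(spec$means, spec$sigma), n = n)
}

# indicator of nearest-mean misclassification for draws from N(from, s^2 I)
pair_errors <- function(from, other, sigma, n) {
  d <- length(from)
  X <- matrix(stats::rnorm(n * d, sd = sigma), nrow = n, ncol = d)
  X <- sweep(X, 2L, from, `+`)
  d_from <- rowSums(sweep(X, 2L, from, `-`)^2)
  d_other <- rowSums(sweep(X, 2L, other, `-`)^2)
  d_other < d_from
}

#' Generate an overlap-calibrated benchmark dataset
#'
#' One-call wrapper: seeds the RNG, calibrates a mixture of `m` spherical
#' Gaussian components in `d` dimensions to average pairwise overlap
#' `omega`, and samples `n` labeled points from it. The two benchmark
#' shapes used throughout are 200 points / 6 features / 5 clusters and
#' 500 points / 7 features / 10 clusters.
#'
#' @inheritParams calibrate_mixture
#' @param n Number of points.
#' @param omega Target average pairwise overlap in `(0, 0.5)`.
#' @param seed Integer seed controlling both calibration and sampling.
#' @return A `"sim_dataset"`; see [sample_mixture()].
#' @examples
#' ds <- simulate_dataset(n = 200, d = 6, m = 5, omega = 0.05, seed = 1)
#' dim(ds$data); table(ds$labels)
#' @export
simulate_dataset <- function(n, d, m, omega, seed = NULL, sigma = 0.1) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  spec <- calibrate_mixture(m, d, omega, sigma = sigma)
  sample_mixture(spec, n)
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Simulated dataset:", nrow(x$data), "points,", ncol(x$data),
      "features,", nrow(x$spec$means), "clusters\n")
  cat("  average pairwise overlap:", signif(x$spec$omega_achieved, 6L), "\n")
  invisible(x)
}
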