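# Shared fixtures, built in code.

# Movie-rating worked example: two raters scoring five movies
person1 <- c(10, 6, 5, 1, 8)
person2 <- c(9, 3, 9, 6, 1)

# Two 3-feature objects realizing the descending rank orders
# (orange, red, blue) and (blue, orange, red)
fig3_a <- c(orange = 0.9, red = 0.6, blue = 0.3)
fig3_b <- c(orange = 0.6, red = 0.3, blue = 0.9)

random_permutation <- function(n) sample.int(n)

# small labeled two-cluster dataset for clustering smoke tests
two_blob_data <- function(n_per = 20, d = 3, sep = 5, seed = 1) {
  set.seed(seed)
  rbind(matrix(stats::rnorm(n_per * d), n_per, d),
        matrix(stats::rnorm(n_per * d, mean = sep), n_per, d))
}

# does the clustering framework with the Euclidean measure reproduce
# Lloyd's k-means from the same Forgy draw? (single restart, matched seed)
framework_matches_kmeans <- function(seed, n = 60, m = 3L) {
  d <- 2L + (seed %% 4L)
  ds <- simulate_dataset(n = n, d = d, m = m, omega = 0.05, seed = seed)
  Xn <- suppressWarnings(min_max_normalize(ds$data))
  fit <- inv_cluster(Xn, m, measure = "euclidean", n_restarts = 1,
                     seed = seed, normalize = FALSE, max_iter = 200)
  set.seed(seed)
  centers <- Xn[sample.int(nrow(Xn), m), , drop = FALSE]
  km <- suppressWarnings(stats::kmeans(Xn, centers = centers,
                                       iter.max = 200,
                                       algorithm = "Lloyd"))
  adjusted_rand_index(fit$labels, km$cluster)
}
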