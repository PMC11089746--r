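# Vectorized inversion-count machinery used by the clustering loop.
#
# With ties broken to total orders, two rankings disagree on feature pair
# (i, j) exactly when sign(rank_a[i] - rank_a[j]) != sign(rank_b[i] -
# rank_b[j]).  Encoding each row as a +/-1 vector over the n(n-1)/2 feature
# pairs turns pairwise inversion counting between two sets of rows into a
# single matrix product:
#   count(a, b) = (P - s_a . s_b) / 2,  P = n(n-1)/2
# and with priority weights w_p = prio_i * prio_j on pair p:
#   weighted(a, b) = (sum(w) - (s_a * w) . s_b) / 2.
# This is what keeps ICA/RIECA at benchmark scale fast in pure R; the
# scalar route (rank_sequence -> relabel -> merge-sort count) is the
# reference the engine is tested against.

# index pairs (i < j) over n features, as a 2-column matrix
feature_pairs <- function(n) {
  which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
}

# per-row rank positions (1 = highest value), ties by tie_order
rank_matrix <- function(X, tie_order = seq_len(ncol(X))) {
  n <- ncol(X)
  precedence <- order(check_permutation(tie_order, n, "tie_order"))
  t(apply(X, 1L, function(v) {
    r <- integer(n)
    r[order(-v, precedence)] <- seq_len(n)
    r
  }))
}

# rows -> {-1,+1} signs over feature pairs
pair_sign_matrix <- function(X, tie_order = seq_len(ncol(X))) {
  R <- rank_matrix(X, tie_order)
  pr <- feature_pairs(ncol(X))
  S <- sign(R[, pr[, 1L], drop = FALSE] - R[, pr[, 2L], drop = FALSE])
  storage.mode(S) <- "double"
  S
}

# (weighted) inversion counts between all rows of A and all rows of B
inversion_count_matrix <- function(SA, SB, pair_weights = NULL) {
  if (is.null(pair_weights)) {
    (ncol(SA) - SA %*% t(SB)) / 2
  } else {
    (sum(pair_weights) - sweep(SA, 2L, pair_weights, `*`) %*% t(SB)) / 2
  }
}

# squared Euclidean distances between all rows of A and all rows of B
cross_dist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  d2[d2 < 0] <- 0  # guard tiny negative round-off
  d2
}

# k x m measure matrix for one of the framework's assignment measures
measure_matrix <- function(X, centroids, measure, pair_weights = NULL,
                           tie_order = seq_len(ncol(X)), SX = NULL) {
  D <- sqrt(cross_dist2(X, centroids))
  if (measure == "euclidean") return(list(M = D, D = D))
  SX <- SX %||% pair_sign_matrix(X, tie_order)
  SC <- pair_sign_matrix(centroids, tie_order)
  INV <- inversion_count_matrix(SX, SC, pair_weights)
  M <- switch(measure, inv = INV, rieca = INV * D)
  list(M = M, D = D)
}
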