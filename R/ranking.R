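#' Rank sequence of a feature vector
#'
#' Orders the feature indices of a numeric vector by descending value, the
#' highest-valued feature first. Exact value ties are broken by `tie_order`:
#' among tied features, the one appearing earlier in `tie_order` is ranked
#' higher. The default tie order is ascending feature index, so ties fall to
#' the lower-numbered feature.
#'
#' @param x Numeric vector of feature values; all values must be finite.
#' @param tie_order Integer permutation of `seq_along(x)` giving the
#'   precedence used to break exact value ties. Default: ascending index.
#' @return Integer vector: a permutation of `seq_along(x)`, position 1
#'   holding the index of the highest-valued feature.
#' @examples
#' rank_sequence(c(10, 6, 5, 1, 8))  # 1 5 2 3 4
#' rank_sequence(c(9, 3, 9, 6, 1))   # 1 3 4 2 5 (tie at 9 -> lower index first)
#' @seealso [inversions()], [relabel()]
#' @export
rank_sequence <- function(x, tie_order = seq_along(x)) {
  x <- check_object_vector(x)
  tie_order <- check_permutation(tie_order, length(x), "tie_order")
  # precedence of feature i = position of i in tie_order; lower wins ties
  precedence <- order(tie_order)
  order(-x, precedence)
}

#' Relabel a rank sequence in a reference sequence's labels
#'
#' Rewrites `other` in the integer labels that `reference` assigns: the
#' feature ranked k-th by `reference` gets label k. Applying a sequence to
#' itself yields the identity permutation, so the inversion count of the
#' relabeled sequence measures how far `other`'s ranking departs from
#' `reference`'s.
#'
#' @param reference,other Integer permutations of the same feature indices,
#'   as returned by [rank_sequence()].
#' @return Integer permutation of `1:n`: `other` written in `reference`'s
#'   labels.
#' @examples
#' p1 <- rank_sequence(c(10, 6, 5, 1, 8))
#' p2 <- rank_sequence(c(9, 3, 9, 6, 1))
#' relabel(p1, p2)  # 1 4 5 3 2
#' @export
relabel <- function(reference, other) {
  n <- length(reference)
  reference <- check_permutation(reference, n, "reference")
  other <- check_permutation(other, n, "other")
  label <- integer(n)
  label[reference] <- seq_len(n)  # feature ranked k-th by reference -> k
  label[other]
}

#' Count inversions in a permutation
#'
#' An inversion is a pair of positions `i < j` with `seq[i] > seq[j]`.
#' Counting is done by merge-sort accumulation in O(n log n); the quadratic
#' reference counter is available as [count_inversions_naive()].
#'
#' @param seq Integer permutation of `1:n`.
#' @return Non-negative integer inversion count, at most `n * (n - 1) / 2`.
#' @examples
#' count_inversions(c(1, 4, 5, 3, 2))  # 5
#' count_inversions(5:1)               # 10
#' @export
count_inversions <- function(seq) {
  seq <- check_permutation(seq, length(seq), "seq")
  merge_count(seq)$count
}

#' Count inversions by exhaustive pair enumeration
#'
#' The O(n^2) double-loop counter, kept as an independent reference for the
#' merge-sort implementation in [count_inversions()].
#'
#' @inheritParams count_inversions
#' @return Non-negative integer inversion count.
#' @export
count_inversions_naive <- function(seq) {
  seq <- check_permutation(seq, length(seq), "seq")
  n <- length(seq)
  total <- 0L
  if (n < 2L) return(total)
  for (i in seq_len(n - 1L)) {
    total <- total + sum(seq[i] > seq[(i + 1L):n])
  }
  as.integer(total)
}

# merge-sort inversion accumulation; returns sorted vector and running count
merge_count <- function(v) {
  n <- length(v)
  if (n < 2L) return(list(sorted = v, count = 0L))
  mid <- n %/% 2L
  left <- merge_count(v[seq_len(mid)])
  right <- merge_count(v[(mid + 1L):n])
  a <- left$sorted
  b <- right$sorted
  na <- length(a)
  nb <- length(b)
  merged <- integer(na + nb)
  count <- left$count + right$count
  i <- 1L; j <- 1L; k <- 1L
  while (i <= na && j <= nb) {
    if (a[i] <= b[j]) {
      merged[k] <- a[i]; i <- i + 1L
    } else {
      # a[i..na] all exceed b[j]: each forms an inversion with b[j]
      merged[k] <- b[j]; j <- j + 1L
      count <- count + (na - i + 1L)
    }
    k <- k + 1L
  }
  if (i <= na) merged[k:(na + nb)] <- a[i:na]
  if (j <= nb) merged[k:(na + nb)] <- b[j:nb]
  list(sorted = merged, count = count)
}

#' Inversions between two objects
#'
#' The Inv dissimilarity of two feature vectors: rank both objects'
#' features (descending value, shared tie order), relabel the second
#' ranking in the first one's labels, and count inversions in the result.
#' Equivalently, the number of feature pairs ranked in opposite relative
#' order by the two objects — a Kendall-style distance between the two
#' rankings. Higher counts mean less similar objects.
#'
#' @param a,b Numeric vectors of equal length over the same features.
#' @param tie_order Integer permutation used to break exact value ties,
#'   applied identically to both objects.
#' @return Object of class `"inversion_result"`: a list with elements
#'   `count` (integer), `weighted_count` (equal to `count` here; see
#'   [adj_inv()] for priority weighting), and `crossing_pairs` (two-column
#'   integer matrix of discordant feature-index pairs, `i < j` per row).
#' @examples
#' p1 <- c(10, 6, 5, 1, 8)
#' p2 <- c(9, 3, 9, 6, 1)
#' inversions(p1, p2)$count  # 5
#' @export
inversions <- function(a, b, tie_order = seq_along(a)) {
  a <- check_object_vector(a, "a")
  b <- check_object_vector(b, "b")
  if (length(a) != length(b)) {
    stop("'a' and 'b' must have the same number of features (",
         length(a), " vs ", length(b), ")", call. = FALSE)
  }
  tie_order <- check_permutation(tie_order, length(a), "tie_order")
  pairs <- crossing_pairs(a, b, tie_order)
  count <- count_inversions(relabel(rank_sequence(a, tie_order),
                                    rank_sequence(b, tie_order)))
  stopifnot(count == nrow(pairs))  # two routes to the same discordance set
  structure(
    list(count = count, weighted_count = as.numeric(count),
         crossing_pairs = pairs),
    class = "inversion_result"
  )
}

#' @export
print.inversion_result <- function(x, ...) {
  cat("Inversions:", x$count, "\n")
  if (x$weighted_count != x$count) {
    cat("Priority-weighted:", x$weighted_count, "\n")
  }
  if (nrow(x$crossing_pairs) > 0) {
    cat("Discordant feature pairs:\n")
    apply(x$crossing_pairs, 1L, function(p) cat("  (", p[1], ",", p[2], ")\n"))
  }
  invisible(x)
}

#' Discordant feature pairs of two objects
#'
#' Enumerates the feature pairs `(i, j)`, `i < j`, whose relative order
#' differs between the two objects' rank sequences — the line crossings of
#' the visual inversion-counting construction.
#'
#' @inheritParams inversions
#' @return Two-column integer matrix, one discordant pair per row.
#' @export
crossing_pairs <- function(a, b, tie_order = seq_along(a)) {
  a <- check_object_vector(a, "a")
  b <- check_object_vector(b, "b")
  if (length(a) != length(b)) {
    stop("'a' and 'b' must have the same number of features", call. = FALSE)
  }
  n <- length(a)
  tie_order <- check_permutation(tie_order, n, "tie_order")
  out <- matrix(integer(0), ncol = 2L,
                dimnames = list(NULL, c("i", "j")))
  if (n < 2L) return(out)
  ra <- rank_of_features(a, tie_order)
  rb <- rank_of_features(b, tie_order)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  disc <- (ra[idx[, 1L]] - ra[idx[, 2L]]) * (rb[idx[, 1L]] - rb[idx[, 2L]]) < 0
  out <- idx[disc, , drop = FALSE]
  dimnames(out) <- list(NULL, c("i", "j"))
  out
}

#' Priority-weighted inversion count
#'
#' Each discordant feature pair contributes the product of the two
#' features' priority weights, instead of 1. With unit priorities this
#' equals the plain inversion count. Increasing any priority can only
#' increase the value.
#'
#' @inheritParams inversions
#' @param priorities Numeric vector of strictly positive per-feature
#'   weights, aligned with the features. Default: all 1.
#' @return Non-negative numeric: sum over discordant pairs of
#'   `priorities[i] * priorities[j]`.
#' @examples
#' # two 3-feature objects whose rankings are (1,2,3) vs (3,1,2):
#' a <- c(0.9, 0.6, 0.3)
#' b <- c(0.6, 0.3, 0.9)
#' adj_inv(a, b)                       # 2 crossings, unit weights -> 2
#' adj_inv(a, b, priorities = c(1, 2, 3))  # 1*3 + 2*3 = 9
#' @export
adj_inv <- function(a, b, priorities = rep(1, length(a)),
                    tie_order = seq_along(a)) {
  a <- check_object_vector(a, "a")
  priorities <- check_priorities(priorities, length(a))
  pairs <- crossing_pairs(a, b, tie_order)
  if (nrow(pairs) == 0L) return(0)
  sum(priorities[pairs[, 1L]] * priorities[pairs[, 2L]])
}

# rank position of each feature (1 = highest value), ties by tie_order
rank_of_features <- function(x, tie_order = seq_along(x)) {
  r <- integer(length(x))
  r[rank_sequence(x, tie_order)] <- seq_along(x)
  r
}
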