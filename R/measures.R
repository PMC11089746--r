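#' Euclidean distance between two feature vectors
#'
#' @param a,b Numeric vectors of equal length with finite values.
#' @return Non-negative numeric; zero iff `a == b`.
#' @examples
#' euclidean_dist(c(0, 0), c(3, 4))  # 5
#' @export
euclidean_dist <- function(a, b) {
  a <- check_object_vector(a, "a")
  b <- check_object_vector(b, "b")
  if (length(a) != length(b)) {
    stop("'a' and 'b' must have the same number of features", call. = FALSE)
  }
  sqrt(sum((a - b)^2))
}

#' Inversion-count dissimilarity (the ICA assignment measure)
#'
#' Dissimilarity of an object and a centroid defined as their
#' (priority-weighted) inversion count: the number of feature pairs the
#' two vectors rank in opposite order. With unit priorities this is the
#' plain inversion count. Larger values mean less similar vectors.
#'
#' @inheritParams adj_inv
#' @return Non-negative numeric.
#' @seealso [adj_inv()], [rieca_measure()], [inv_cluster()]
#' @export
inv_measure <- function(a, b, priorities = rep(1, length(a)),
                        tie_order = seq_along(a)) {
  adj_inv(a, b, priorities = priorities, tie_order = tie_order)
}

#' Inversion-regulated Euclidean dissimilarity (the RIECA assignment measure)
#'
#' The Euclidean distance multiplied by the (priority-weighted) inversion
#' count, so the inversion count acts as a regulator: many discordant
#' feature pairs inflate the distance, while identically ranked vectors
#' yield zero regardless of their Euclidean separation.
#'
#' @inheritParams adj_inv
#' @return Non-negative numeric, zero when either factor is zero.
#' @seealso [inv_measure()], [inv_cluster()]
#' @export
rieca_measure <- function(a, b, priorities = rep(1, length(a)),
                          tie_order = seq_along(a)) {
  inv_measure(a, b, priorities = priorities, tie_order = tie_order) *
    euclidean_dist(a, b)
}

# closed set of assignment measures usable by the clustering framework
measure_kinds <- c("rieca", "inv", "euclidean")

check_measure <- function(measure) {
  match.arg(measure, measure_kinds)
}
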