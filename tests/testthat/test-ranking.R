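test_that("rank sequences order features by descending value with index tie-break", {
  expect_equal(rank_sequence(person1), c(1L, 5L, 2L, 3L, 4L))
  # rater 2 ties movies 1 and 3 at 9; lower index wins
  expect_equal(rank_sequence(person2), c(1L, 3L, 4L, 2L, 5L))
  expect_equal(rank_sequence(c(7, 7, 7)), 1:3)
  # a custom tie order reverses which tied feature comes first
  expect_equal(rank_sequence(c(7, 7, 7), tie_order = 3:1), 3:1)
})

test_that("rank_sequence rejects non-finite values, naming the feature", {
  expect_error(rank_sequence(c(1, NA, 3)), "non-finite")
  expect_error(rank_sequence(c(a = 1, b = Inf)), "\\bb\\b")
  expect_error(rank_sequence(numeric(0)), "non-empty")
})

test_that("relabel rewrites a sequence in the reference's labels", {
  r1 <- rank_sequence(person1)
  r2 <- rank_sequence(person2)
  expect_equal(relabel(r1, r2), c(1L, 4L, 5L, 3L, 2L))
  expect_equal(relabel(r1, r1), 1:5)
  # hand-relabeled 3-feature case: reference ranks (1,2,3), other (3,1,2)
  expect_equal(relabel(c(1L, 2L, 3L), c(3L, 1L, 2L)), c(3L, 1L, 2L))
  # brute-force position lookup agrees on random pairs
  set.seed(11)
  for (i in 1:20) {
    n <- sample(2:10, 1)
    ref <- random_permutation(n)
    oth <- random_permutation(n)
    lookup <- vapply(oth, function(f) which(ref == f), 1L)
    expect_equal(relabel(ref, oth), lookup)
  }
  expect_error(relabel(1:3, 1:4), "permutation")
})

test_that("merge-sort inversion counter matches printed and closed-form cases", {
  expect_equal(count_inversions(c(1L, 4L, 5L, 3L, 2L)), 5L)
  expect_equal(count_inversions(1:10), 0L)
  for (n in c(2L, 5L, 17L)) {
    expect_equal(count_inversions(rev(seq_len(n))), n * (n - 1L) / 2L)
  }
  expect_error(count_inversions(c(1L, 1L, 2L)), "permutation")
})

test_that("merge-sort counter equals the double-loop oracle on random permutations", {
  set.seed(42)
  for (i in seq_len(1000)) {
    n <- sample(2:50, 1)
    p <- random_permutation(n)
    expect_identical(count_inversions(p), count_inversions_naive(p))
  }
})

test_that("inversion counts are bounded and maximal only for reversals", {
  set.seed(7)
  for (i in 1:100) {
    n <- sample(2:12, 1)
    p <- random_permutation(n)
    cnt <- count_inversions(p)
    expect_gte(cnt, 0L)
    expect_lte(cnt, n * (n - 1L) / 2L)
    if (cnt == n * (n - 1L) / 2L) expect_equal(p, rev(seq_len(n)))
  }
})

test_that("object-pair inversions match the worked movie example", {
  res <- inversions(person1, person2)
  expect_s3_class(res, "inversion_result")
  expect_equal(res$count, 5L)
  expect_equal(res$weighted_count, 5)
  expect_equal(nrow(res$crossing_pairs), 5L)
  expect_equal(inversions(person1, person1)$count, 0L)
  expect_error(inversions(1:3, 1:4), "same number of features")
})

test_that("inversion count equals the brute-force pairwise-crossing oracle", {
  set.seed(23)
  for (i in 1:50) {
    a <- stats::rnorm(8)
    b <- stats::rnorm(8)
    ra <- order(order(-a))  # rank position per feature, no ties w.p. 1
    rb <- order(order(-b))
    disc <- 0L
    for (p in 1:7) for (q in (p + 1):8) {
      if ((ra[p] - ra[q]) * (rb[p] - rb[q]) < 0) disc <- disc + 1L
    }
    expect_equal(inversions(a, b)$count, disc)
  }
})

test_that("inversions are symmetric in their arguments, including under ties", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(2:10, 1)
    a <- sample(1:4, n, replace = TRUE)  # coarse values force ties
    b <- sample(1:4, n, replace = TRUE)
    expect_equal(inversions(a, b)$count, inversions(b, a)$count)
  }
})

test_that("priority weighting reproduces the two worked configurations", {
  expect_equal(adj_inv(fig3_a, fig3_b), 2)
  expect_equal(adj_inv(fig3_a, fig3_b, priorities = c(1, 2, 3)), 9)
  expect_equal(adj_inv(fig3_a, fig3_a, priorities = c(5, 1, 2)), 0)
  expect_equal(adj_inv(person1, person2), 5)
  expect_error(adj_inv(fig3_a, fig3_b, priorities = c(1, 0, 3)),
               "positive")
})

test_that("raising any single priority never decreases the weighted count", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(3:8, 1)
    a <- stats::rnorm(n)
    b <- stats::rnorm(n)
    w <- stats::runif(n, 0.5, 2)
    base <- adj_inv(a, b, priorities = w)
    j <- sample(n, 1)
    w2 <- w
    w2[j] <- w[j] + stats::runif(1, 0.1, 2)
    expect_gte(adj_inv(a, b, priorities = w2), base)
  }
})

test_that("equal Euclidean shifts can yield unequal inversion counts", {
  # adding v to a feature reorders the ranking; subtracting it does not
  o1 <- c(5, 4)
  o2 <- c(7, 4)  # +2 on feature 1
  o3 <- c(3, 4)  # -2 on feature 1
  expect_equal(euclidean_dist(o1, o2), euclidean_dist(o1, o3))
  expect_equal(inversions(o1, o2)$count, 0L)
  expect_equal(inversions(o1, o3)$count, 1L)
})
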