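# invclust

Rank-inversion similarity and inversion-based partitioning clustering
for numeric feature data.

## The problem

Euclidean-style measures compare feature vectors value by value, which
builds in three assumptions that often fail in practice: adding or
subtracting the same amount to a feature changes the distance
identically (symmetry), the change is the same whichever feature it
lands on (place symmetry), and features never influence each other's
contribution (independence). For profile-like data — raters scoring
items, hospitals ranked on indicators, expression panels — what matters
is *which features dominate which*, not raw coordinate gaps.

`invclust` implements a rank-based dissimilarity and the clustering
algorithms built on it, for analysts clustering moderate-dimensional
numeric data whose cluster structure lives in feature orderings:

* **Inv** — order each object's features by descending value (ties to a
  fixed feature order) and count the feature pairs the two objects rank
  oppositely. For rank sequences `\pi_a, \pi_b` over `n` features,
  `Inv(a, b) = #\{(i, j) : i < j, \text{discordant}\} \le n(n-1)/2` — a
  Kendall-style distance, counted in O(n log n) by merge sort.
* **AdjInv** — each discordant pair `(i, j)` weighted by
  `priority(i) * priority(j)`, for feature prioritization.
* **ICA** — k-means-style partitioning (min-max normalize, assign to
  the centroid with the fewest inversions, recenter by cluster means).
* **RIECA** — same framework with measure
  `Inv(obj, c) \times E(obj, c)`: the inversion count regulating the
  Euclidean distance.

Alongside: a spherical Gaussian-mixture generator calibrated to a target
average pairwise overlap (the clustering-difficulty knob), a
Hubert–Arabie adjusted Rand index, and a benchmark harness comparing
ICA/RIECA with k-means, model-based EM, hierarchical, and k-medoids
baselines.

## Worked example

```r
library(invclust)

p1 <- c(10, 6, 5, 1, 8)   # rater 1's scores of five movies
p2 <- c(9, 3, 9, 6, 1)    # rater 2; movies 1 and 3 tied at 9

rank_sequence(p1)                          # 1 5 2 3 4
rank_sequence(p2)                          # 1 3 4 2 5  (tie -> lower index)
relabel(rank_sequence(p1), rank_sequence(p2))  # 1 4 5 3 2
inversions(p1, p2)$count                   # 5

a <- c(orange = 0.9, red = 0.6, blue = 0.3)   # ranking orange, red, blue
b <- c(orange = 0.6, red = 0.3, blue = 0.9)   # ranking blue, orange, red
adj_inv(a, b)                              # 2   (two crossings, unit weights)
adj_inv(a, b, priorities = c(1, 2, 3))     # 9   (1*3 + 2*3)

ds  <- simulate_dataset(n = 200, d = 6, m = 5, omega = 0.05, seed = 1)
fit <- rieca(ds$data, m = 5, seed = 1)
fit
#> RIECA clustering: 5 clusters, 200 objects
#>   objective: 202.4618   iterations: 8 (converged)
#>   cluster sizes: 49, 46, 28, 34, 43
adjusted_rand_index(ds$labels, fit$labels)
#> [1] 0.5012997
```

The two rank sequences cross five times, so the raters' Inv
dissimilarity is 5 of a possible 10; the priority-weighted variant
multiplies each crossing by the two features' weights. The clustering
fit recovers a moderately overlapped five-cluster mixture
(average pairwise overlap 0.05) with ARI 0.50 against the generating
labels.

A small benchmark:

```r
run_benchmark(families = 1, omegas = c(0.4, 0.001),
              algorithms = c("rieca", "kmeans"), reps = 20, seed = 1)
#> Clustering benchmark: 20 replicates per cell
#>
#>  family omega algorithm  mean    sd reps
#>       1 0.001    kmeans 0.994 0.009   20
#>       1 0.400    kmeans 0.108 0.030   20
#>       1 0.001     rieca 0.961 0.031   20
#>       1 0.400     rieca 0.094 0.037   20
```

A command-line front end over the same functions is installed at
`inst/cli/invclust.R` (subcommands `cluster`, `simulate`, `benchmark`,
`crossings`).

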