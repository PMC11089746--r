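Package: invclust
Title: Inversion-Based Similarity and Partitioning Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Rank-inversion (Kendall-style) dissimilarity between numeric
    feature vectors, with optional per-feature priority weighting, and the
    partitioning clustering algorithms built on it: ICA (assignment by
    inversion count) and RIECA (assignment by inversion count times
    Euclidean distance). Includes an overlap-calibrated spherical
    Gaussian-mixture benchmark generator, an adjusted Rand index
    implementation, and a benchmark harness comparing the inversion-based
    algorithms against k-means, model-based EM, hierarchical, and
    k-medoids baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mclust,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
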