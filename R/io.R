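#' Read a feature dataset from CSV
#'
#' Expects a header row naming the features; every column must be numeric
#' except an optional `label` column holding ground-truth cluster
#' identifiers, which is kept aside for evaluation and never used for
#' fitting. Row order is preserved.
#'
#' @param path Path to a comma-separated file with a header.
#' @return List with `data` (numeric matrix, feature names as column
#'   names), `feature_ids` (character), and `labels` (vector or `NULL`).
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L || ncol(df) == 0L) {
    stop("empty dataset: ", path, call. = FALSE)
  }
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- df[["label"]]
    df <- df[, setdiff(names(df), "label"), drop = FALSE]
  }
  if (ncol(df) == 0L) stop("no feature columns in ", path, call. = FALSE)
  for (col in names(df)) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad) > 0L) {
      stop("non-numeric or non-finite value in '", path, "' at row ",
           bad[1L], ", column '", col, "'", call. = FALSE)
    }
    df[[col]] <- v
  }
  X <- as.matrix(df)
  list(data = X, feature_ids = colnames(X), labels = labels)
}

#' Write cluster labels to CSV
#'
#' Writes a two-column CSV (`object_id`, `cluster`). Refuses to overwrite
#' an existing file unless `force = TRUE`.
#'
#' @param labels Integer vector of cluster labels.
#' @param path Output path.
#' @param force Overwrite an existing file (default `FALSE`).
#' @return Invisibly, `path`.
#' @export
write_labels <- function(labels, path, force = FALSE) {
  if (file.exists(path) && !force) {
    stop("refusing to overwrite existing file: ", path,
         " (use force = TRUE)", call. = FALSE)
  }
  utils::write.csv(
    data.frame(object_id = seq_along(labels), cluster = labels),
    path, row.names = FALSE)
  invisible(path)
}

#' Read cluster labels written by [write_labels()]
#'
#' @param path Path to the label CSV.
#' @return Integer vector of cluster labels in object order.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("object_id", "cluster") %in% names(df))) {
    stop("'", path, "' is not a label CSV (object_id, cluster)",
         call. = FALSE)
  }
  df$cluster[order(df$object_id)]
}

#' Write a clustering result or benchmark report as JSON
#'
#' Serializes an `"inv_cluster"` fit (centroids, objective, iteration
#' count, convergence, configuration) or a `"benchmark_report"` to a JSON
#' sidecar with a schema version, so runs are fully reconstructible.
#'
#' @param x An `"inv_cluster"` or `"benchmark_report"` object.
#' @param path Output path.
#' @param force Overwrite an existing file (default `FALSE`).
#' @return Invisibly, `path`.
#' @export
write_result_json <- function(x, path, force = FALSE) {
  if (file.exists(path) && !force) {
    stop("refusing to overwrite existing file: ", path,
         " (use force = TRUE)", call. = FALSE)
  }
  payload <- if (inherits(x, "inv_cluster")) {
    list(schema = "invclust/clustering/1",
         measure = x$measure, m = x$m, seed = x$seed,
         n_iter = x$n_iter, converged = x$converged,
         degenerate = x$degenerate, objective = x$objective,
         restart_objectives = x$restart_objectives,
         centroids = unname(apply(x$centroids, 1L, as.numeric,
                                  simplify = FALSE)))
  } else if (inherits(x, "benchmark_report")) {
    list(schema = "invclust/benchmark/1",
         config = x$config, summary = x$summary, anova = x$anova,
         best = x$best)
  } else {
    stop("don't know how to serialize an object of class ",
         paste(class(x), collapse = "/"), call. = FALSE)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
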