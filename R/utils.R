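# input validation helpers shared across modules

check_object_vector <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) < 1L) {
    stop("'", name, "' must be a non-empty numeric vector", call. = FALSE)
  }
  bad <- which(!is.finite(x))
  if (length(bad) > 0L) {
    lab <- if (!is.null(names(x))) names(x)[bad[1L]] else bad[1L]
    stop("'", name, "' contains a non-finite value at feature ", lab,
         call. = FALSE)
  }
  as.numeric(x)
}

check_permutation <- function(p, n, name = "permutation") {
  if (!is.numeric(p) || length(p) != n || anyNA(p) ||
      any(p != as.integer(p)) || !setequal(p, seq_len(n))) {
    stop("'", name, "' must be a permutation of 1:", n, call. = FALSE)
  }
  as.integer(p)
}

check_priorities <- function(priorities, n) {
  if (!is.numeric(priorities) || length(priorities) != n ||
      anyNA(priorities) || any(!is.finite(priorities))) {
    stop("'priorities' must be a numeric vector of length ", n,
         call. = FALSE)
  }
  if (any(priorities <= 0)) {
    stop("'priorities' must all be strictly positive", call. = FALSE)
  }
  as.numeric(priorities)
}

check_matrix <- function(X, name = "data") {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X) || nrow(X) < 1L || ncol(X) < 1L) {
    stop("'", name, "' must be a non-empty numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)[1L, ]
    stop("'", name, "' has a non-finite value at row ", bad[1L],
         ", column ", bad[2L], call. = FALSE)
  }
  X
}

`%||%` <- function(a, b) if (is.null(a)) b else a
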