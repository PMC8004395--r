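# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package code never
#' perturbs the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream index, kept < 2^31.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 1000003 + 7919 * stream) %% 2147483629 + 1
}

# Row-wise softmax of a matrix of log-weights, numerically stable.
softmax_rows <- function(logw) {
  m <- apply(logw, 1L, max)
  w <- exp(logw - m)
  w / rowSums(w)
}

# log(sum(exp(x))) per row, numerically stable.
logsumexp_rows <- function(logw) {
  m <- apply(logw, 1L, max)
  m + log(rowSums(exp(logw - m)))
}

# Check a square symmetric nonnegative zero-diagonal distance matrix.
check_dist_matrix <- function(d, what = "distance matrix") {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop(what, " must be a square matrix", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8)
    stop(what, " must be symmetric", call. = FALSE)
  if (any(diag(d) != 0))
    stop(what, " must have a zero diagonal", call. = FALSE)
  if (any(d < -1e-12))
    stop(what, " must be nonnegative", call. = FALSE)
  invisible(d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
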