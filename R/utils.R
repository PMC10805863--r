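#' @keywords internal
#' @useDynLib deeframe, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

# Shared small helpers: argument checks, seeded evaluation, numerics.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, msg, ...) {
  if (isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `code` with the random-number generator seeded to `seed`, then
#' restores the caller's RNG state, so seeded generators never perturb the
#' surrounding random stream.
#'
#' @param seed Integer scalar seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  stop_if(!is.numeric(seed) || length(seed) != 1L || is.na(seed),
          "seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Numerically stable softmax over the rows of a matrix
#' @param x Numeric matrix (or vector, treated as one row).
#' @return Matrix of the same shape whose rows sum to 1.
#' @export
softmax <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

# classification metrics with "high" as the positive class
classification_metrics <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  truth <- as.integer(truth)
  pred <- as.integer(pred)
  tp <- sum(truth == 1L & pred == 1L)
  fp <- sum(truth == 0L & pred == 1L)
  fn <- sum(truth == 1L & pred == 0L)
  acc <- mean(truth == pred)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && (prec + rec) > 0) {
    2 * prec * rec / (prec + rec)
  } else NA_real_
  c(accuracy = acc, precision = prec, recall = rec, f1 = f1)
}
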