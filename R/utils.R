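# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed, restoring global RNG state
#'
#' All stochastic entry points in the package route their randomness through
#' this helper so that a user-supplied seed gives bit-identical results and
#' the caller's RNG stream is left untouched.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible child seed from a root seed and a stage label.
# Keeps every stage on its own substream while staying inside 32-bit range.
derive_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  v <- utf8ToInt(label)
  h <- sum(v * seq_along(v)) %% 100003L
  as.integer((abs(as.double(seed)) %% 20000 + 1) * 100003 + h)
}

#' Stratified cross-validation fold assignment
#'
#' Assigns each observation to one of `k` folds. For a binary outcome the
#' assignment is stratified by class so every training fold sees both
#' classes whenever the data allow it.
#'
#' @param y Outcome vector (binary 0/1 or continuous).
#' @param k Number of folds.
#' @param seed Optional integer seed.
#' @return Integer vector of fold ids in `1..k`.
#' @keywords internal
make_folds <- function(y, k, seed = NULL, stratify = TRUE) {
  n <- length(y)
  if (k < 2) stop("need at least 2 folds")
  if (k > n) stop("more folds than observations")
  with_seed(seed, {
    fold <- integer(n)
    classes <- if (stratify && length(unique(y)) == 2) unique(y) else NA
    if (length(classes) == 2 && !anyNA(classes)) {
      for (cl in classes) {
        idx <- which(y == cl)
        fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    } else {
      fold <- sample(rep_len(seq_len(k), n))
    }
    fold
  })
}

# Logistic helpers
logit <- function(p) log(p / (1 - p))
expit <- function(x) 1 / (1 + exp(-x))

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration [%s]: %s", field, msg), call. = FALSE)
}
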