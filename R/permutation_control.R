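# Chance-association control for the genetic selection procedure: the
# whole step-down selection is refit on datasets in which the block of
# (outcome + non-genetic covariates) rows is permuted as a unit against
# the genotype rows, and the observed model's CVE is compared with the
# permutation null distribution of final-model CVEs.

#' Permute outcome and covariates jointly against genotypes
#'
#' Applies one row permutation to the outcome together with the base
#' covariate block, leaving genotype rows in place: outcome-covariate
#' relationships are preserved exactly while outcome-genotype links are
#' broken. Per-SNP genotype counts are untouched.
#'
#' @param data Selection input list (`y`, `base_x`, `candidates`) as from
#'   [stepdown_data()].
#' @param perm Optional explicit permutation of `seq_along(y)`; drawn
#'   uniformly at random under `seed` when omitted.
#' @param seed Integer seed used when `perm` is missing.
#' @return The input list with `y` and `base_x` rows permuted.
#' @export
permute_dataset <- function(data, perm = NULL, seed = NULL) {
  n <- length(data$y)
  if (is.null(perm)) {
    perm <- with_seed(seed, sample.int(n))
  }
  stopifnot(length(perm) == n, all(sort(perm) == seq_len(n)))
  data$y <- data$y[perm]
  if (!is.null(data$base_x)) {
    data$base_x <- data$base_x[perm, , drop = FALSE]
  }
  data
}

#' Permutation null distribution for step-down selection CVE
#'
#' For each of `n_perm` permuted datasets ([permute_dataset()]) the full
#' step-down selection is rerun with the same penalty grid and CV
#' settings (folds re-drawn from the permutation's own seed stream), and
#' the final-model CVE recorded. The observed model is judged better than
#' chance when its CVE falls below the 25th percentile of the null
#' distribution; an empirical p-value
#' `(1 + #{null CVE <= observed}) / (n_perm + 1)` is reported alongside.
#' Permutations whose selection fails are skipped and counted; at least
#' 90% must succeed.
#'
#' @param data Selection input list from [stepdown_data()].
#' @param observed Optional [stepdown_select()] result for the unpermuted
#'   data; computed when omitted.
#' @param n_perm Number of permutations (>= 20).
#' @param k_grid,folds,repeats,seed Selection settings (shared with the
#'   observed fit).
#' @return Object of class `"null_distribution"`: `observed_cve`,
#'   `null_cve` (vector), `median`, `q25`, `q75`, `verdict`
#'   (`"better_than_chance"` or `"not_better"`), `p_value`, `n_failed`.
#' @export
null_cve <- function(data, observed = NULL, n_perm = 200,
                     k_grid = seq(0, 10, by = 0.1), folds = 10, repeats = 5,
                     seed = 1) {
  if (n_perm < 20) stop("n_perm must be at least 20")
  if (is.null(observed)) {
    observed <- stepdown_select(data$y, data$base_x, data$candidates,
                                k_grid = k_grid, folds = folds,
                                repeats = repeats, seed = seed,
                                family = data$family %||% "binomial")
  }
  vals <- rep(NA_real_, n_perm)
  for (b in seq_len(n_perm)) {
    perm_seed <- derive_seed(seed, paste0("permctl", b))
    pd <- permute_dataset(data, seed = perm_seed)
    res <- tryCatch(
      stepdown_select(pd$y, pd$base_x, pd$candidates, k_grid = k_grid,
                      folds = folds, repeats = repeats,
                      seed = derive_seed(perm_seed, "inner"),
                      family = data$family %||% "binomial"),
      error = function(e) NULL)
    if (!is.null(res)) vals[b] <- res$cve
  }
  ok <- !is.na(vals)
  if (mean(ok) < 0.9) {
    stop(sprintf("only %d/%d permutations produced a selection", sum(ok), n_perm))
  }
  nulls <- vals[ok]
  q <- stats::quantile(nulls, c(0.25, 0.5, 0.75), names = FALSE)
  structure(list(
    observed_cve = observed$cve, observed = observed,
    null_cve = nulls, q25 = q[1], median = q[2], q75 = q[3],
    verdict = if (observed$cve < q[1]) "better_than_chance" else "not_better",
    p_value = (1 + sum(nulls <= observed$cve)) / (length(nulls) + 1),
    n_perm = n_perm, n_failed = sum(!ok)
  ), class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Permutation control (%d permutations, %d failed)\n",
              x$n_perm, x$n_failed))
  cat(sprintf("  observed CVE %.4g vs null median %.4g (25-75%%: %.4g-%.4g)\n",
              x$observed_cve, x$median, x$q25, x$q75))
  cat(sprintf("  verdict: %s (empirical p = %.4g)\n", x$verdict, x$p_value))
  invisible(x)
}
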