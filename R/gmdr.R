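# Generalized multifactor dimensionality reduction (GMDR). Epistasis
# search over multilocus genotype cells using covariate-adjusted score
# residuals: cells are pooled into high/low risk by the sign of their
# summed training scores, and locus sets are ranked by cross-validated,
# score-weighted testing accuracy with a permutation null for calibration.

#' Covariate-adjusted per-subject scores for GMDR
#'
#' Fits the covariate-only (base) model and returns the score residuals
#' `s_i = y_i - fitted probability`. At the maximum-likelihood fit the
#' residuals sum to zero, so the scores are centred; their sign carries
#' the outcome information left unexplained by the non-genetic model.
#'
#' @param y Binary outcome (0/1 or logical).
#' @param base_x Matrix of base-model covariate columns, or `NULL` for an
#'   intercept-only adjustment.
#' @return Numeric vector of scores.
#' @export
score_residuals <- function(y, base_x = NULL) {
  y <- as.numeric(y)
  fit <- fit_glm_matrix(y, if (is.null(base_x)) NULL else as.matrix(base_x),
                        "binomial")
  # a boundary fit (perfect prediction) is a legitimate degenerate case;
  # only a genuinely unconverged interior fit is an error
  if (!fit$converged && fit$deviance > 1e-6) {
    stop("base model did not converge")
  }
  y - fit$fitted.values
}

# Cell assignment for a locus combination: integer cell id per subject,
# NA when any genotype in the combination is missing.
cell_ids <- function(G, loci) {
  id <- rep(0L, nrow(G))
  ok <- rep(TRUE, nrow(G))
  for (j in seq_along(loci)) {
    g <- G[, loci[j]]
    ok <- ok & !is.na(g)
    id <- id * 3L + ifelse(is.na(g), 0L, as.integer(g))
  }
  id[!ok] <- NA_integer_
  id
}

# Weighted testing accuracy of one combination on one CV split.
split_accuracy <- function(s, cell, test) {
  train_sum <- tapply(s[!test & !is.na(cell)], cell[!test & !is.na(cell)], sum)
  if (!length(train_sum)) return(NA_real_)
  lab <- train_sum > 0  # high-risk cells
  te <- which(test & !is.na(cell))
  te_lab <- lab[as.character(cell[te])]
  known <- !is.na(te_lab)
  if (!any(known)) return(NA_real_)
  si <- s[te][known]
  match_hi <- te_lab[known] == (si >= 0)
  sum(abs(si)[match_hi]) / sum(abs(si))
}

#' GMDR search over locus combinations
#'
#' For each combination of `order` SNPs and each cross-validation split:
#' training subjects are pooled into multilocus genotype cells; a cell is
#' labelled high-risk when the sum of its training scores is positive;
#' testing accuracy is the proportion of held-out score mass
#' `sum(|s_i|)` lying in cells whose label matches `sign(s_i)`, over
#' held-out subjects falling in cells seen during training. Per order,
#' the best combination maximises mean testing accuracy across splits,
#' and its cross-validation consistency counts the splits in which it was
#' also the split-best combination. Subjects with a missing genotype are
#' excluded only from combinations involving that SNP.
#'
#' @param scores Per-subject scores from [score_residuals()].
#' @param genotypes Data frame/matrix of 0/1/2 genotype columns (NA
#'   allowed).
#' @param orders Integer vector of interaction orders to search (1 = main
#'   effects, 2 = pairs, ...).
#' @param folds Number of CV splits.
#' @param seed Integer seed for the split draw.
#' @return List of class `"gmdr_result"`, one element per order, each
#'   with `loci`, `testing_accuracy`, `cv_consistency`, `folds`,
#'   `cell_labels` (full-data high/low/empty per cell) and the per-
#'   combination accuracy table (`combinations`).
#' @export
gmdr_search <- function(scores, genotypes, orders = 1:2, folds = 10,
                        seed = 1) {
  G <- as.matrix(genotypes)
  s <- as.numeric(scores)
  stopifnot(nrow(G) == length(s))
  if (max(orders) > ncol(G)) stop("order exceeds the number of SNPs")
  if (length(s) < folds) stop("need at least `folds` subjects")
  pos <- s >= 0
  # stratify splits by score sign when both sides are populous enough
  foldid <- make_folds(as.numeric(pos), folds,
                       seed = derive_seed(seed, "gmdr"),
                       stratify = min(sum(pos), sum(!pos)) >= folds)
  out <- list()
  for (ord in orders) {
    combos <- utils::combn(colnames(G), ord, simplify = FALSE)
    acc <- matrix(NA_real_, length(combos), folds)
    for (ci in seq_along(combos)) {
      cell <- cell_ids(G, combos[[ci]])
      for (f in seq_len(folds)) {
        acc[ci, f] <- split_accuracy(s, cell, foldid == f)
      }
    }
    mean_acc <- rowMeans(acc, na.rm = TRUE)
    best <- which.max(mean_acc)
    split_best <- apply(acc, 2, which.max)
    cell <- cell_ids(G, combos[[best]])
    full_sum <- tapply(s[!is.na(cell)], cell[!is.na(cell)], sum)
    out[[as.character(ord)]] <- list(
      order = ord,
      loci = combos[[best]],
      testing_accuracy = mean_acc[best],
      cv_consistency = sum(split_best == best),
      folds = folds,
      cell_labels = ifelse(full_sum > 0, "high", "low"),
      combinations = data.frame(
        loci = vapply(combos, paste, character(1), collapse = "+"),
        testing_accuracy = mean_acc)
    )
  }
  structure(out, class = "gmdr_result")
}

#' @export
print.gmdr_result <- function(x, ...) {
  cat("GMDR search\n")
  for (r in x) {
    cat(sprintf("  order %d: %s  accuracy %.3f  consistency %d/%d\n",
                r$order, paste(r$loci, collapse = "+"),
                r$testing_accuracy, r$cv_consistency, r$folds))
  }
  invisible(x)
}

#' Permutation null for the GMDR testing accuracy
#'
#' Permutes the score vector against the genotype rows (breaking any
#' genotype-outcome link while preserving both marginals), reruns the
#' search at the given order, and records the best testing accuracy of
#' each permuted dataset. The empirical p-value uses the add-one rule
#' `(1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param scores,genotypes,folds,seed As in [gmdr_search()].
#' @param order Single interaction order to test.
#' @param n_perm Number of permutations (>= 1).
#' @return List of class `"gmdr_null"` with `observed` (the observed best
#'   accuracy), `null_accuracy` (vector), `p_value`, `order`.
#' @export
gmdr_null <- function(scores, genotypes, order, n_perm = 200, seed = 1) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  obs <- gmdr_search(scores, genotypes, orders = order, folds = 10,
                     seed = seed)[[as.character(order)]]
  null_acc <- with_seed(derive_seed(seed, "gmdrnull"), {
    vapply(seq_len(n_perm), function(b) {
      sp <- sample(scores)
      gmdr_search(sp, genotypes, orders = order, folds = 10,
                  seed = derive_seed(seed, paste0("perm", b))
      )[[as.character(order)]]$testing_accuracy
    }, numeric(1))
  })
  structure(list(observed = obs$testing_accuracy, loci = obs$loci,
                 null_accuracy = null_acc,
                 p_value = (1 + sum(null_acc >= obs$testing_accuracy)) /
                   (n_perm + 1),
                 order = order, n_perm = n_perm),
            class = "gmdr_null")
}

#' @export
print.gmdr_null <- function(x, ...) {
  cat(sprintf(
    "GMDR permutation null (order %d, %d permutations)\n", x$order, x$n_perm))
  cat(sprintf("  observed best accuracy %.3f (%s); null median %.3f; p = %.4g\n",
              x$observed, paste(x$loci, collapse = "+"),
              stats::median(x$null_accuracy), x$p_value))
  invisible(x)
}
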