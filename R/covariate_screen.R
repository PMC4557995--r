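# Lasso screening of non-genetic predictors. Candidate design: all
# clinical covariates (registry-transformed and standardized) plus the
# first-order interaction of each with standardized log10 serum fentanyl
# concentration. Regularisation strength is chosen by cross-validation
# with the one-standard-error rule; nonzero terms are the "major
# non-genetic predictors" fixed as the base model downstream.

#' Build the standardized non-genetic candidate design for one outcome
#'
#' Restricts to complete-case rows for the outcome and the candidate
#' covariates, applies the registry transform to each continuous
#' covariate, standardizes to mean 0 / SD 1, indicator-codes categorical
#' covariates (reference level dropped, indicators standardized), and adds
#' an interaction column (elementwise product) of each standardized
#' covariate with standardized log10 serum fentanyl concentration.
#' Zero-variance columns are dropped and recorded.
#'
#' @param cohort Cohort data frame with phenotype columns (see
#'   [add_phenotypes()]).
#' @param outcome Outcome column name.
#' @param covariates Candidate covariate names; default the screened
#'   clinical covariates.
#' @return List with `x` (design matrix), `y` (outcome 0/1 or numeric),
#'   `rows` (row indices of the cohort used), `dropped` (zero-variance
#'   columns removed).
#' @export
build_design <- function(cohort, outcome,
                         covariates = intersect(
                           cohort_covariate_names(candidates_only = TRUE),
                           names(cohort))) {
  if (!outcome %in% names(cohort)) stop("unknown outcome column: ", outcome)
  df <- as.data.frame(cohort)[, c(outcome, covariates), drop = FALSE]
  rows <- which(stats::complete.cases(df))
  df <- df[rows, , drop = FALSE]
  if (!nrow(df)) stop("no complete-case rows for outcome ", outcome)

  std <- function(x) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) return(NULL)
    (x - mean(x)) / s
  }
  cols <- list()
  dropped <- character(0)
  for (v in covariates) {
    x <- df[[v]]
    if (is.numeric(x)) {
      z <- std(apply_transform(registry_transform(v), x))
      if (is.null(z)) dropped <- c(dropped, v) else cols[[v]] <- z
    } else if (is.logical(x)) {
      z <- std(as.numeric(x))
      if (is.null(z)) dropped <- c(dropped, v) else cols[[v]] <- z
    } else {
      x <- factor(x)
      lev <- levels(droplevels(x))
      if (length(lev) < 2) { dropped <- c(dropped, v); next }
      for (l in lev[-1]) {
        nm <- paste0(v, ":", l)
        z <- std(as.numeric(x == l))
        if (is.null(z)) dropped <- c(dropped, nm) else cols[[nm]] <- z
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)

  conc <- cols[["serum_fentanyl_nM"]]
  if (!is.null(conc)) {
    main <- setdiff(colnames(X), "serum_fentanyl_nM")
    inter <- X[, main, drop = FALSE] * conc
    colnames(inter) <- paste0(main, " x log10(fentanyl)")
    keep <- apply(inter, 2, stats::sd) > 0
    dropped <- c(dropped, colnames(inter)[!keep])
    X <- cbind(X, inter[, keep, drop = FALSE])
  }

  y <- df[[outcome]]
  if (is.logical(y)) y <- as.numeric(y)
  list(x = X, y = y, rows = rows, dropped = dropped)
}

#' Lasso screen for major non-genetic predictors
#'
#' L1-penalised binomial (or gaussian, for a continuous outcome)
#' regression over a regularisation path, with the penalty chosen by
#' k-fold cross-validation under the one-standard-error rule. Terms with
#' nonzero coefficients at the chosen penalty are returned as the major
#' non-genetic predictors. Folds are stratified for binary outcomes and
#' fixed by the seed, so the selection is reproducible.
#'
#' @param design A design list from [build_design()].
#' @param folds Number of CV folds.
#' @param seed Integer seed for the fold assignment.
#' @param family `"binomial"` or `"gaussian"`.
#' @param rule `"1se"` (default, parsimonious) or `"min"`.
#' @return Object of class `"screen_result"`: `selected` (term names),
#'   `lambda`, `coefficients` (at the chosen penalty), `n`, `cvm_path`
#'   summary and `dropped` columns.
#' @export
lasso_screen <- function(design, folds = 10, seed = 1, family = "binomial",
                         rule = c("1se", "min")) {
  rule <- match.arg(rule)
  y <- design$y
  if (length(y) < 50) stop("need at least 50 complete rows for screening")
  if (family == "binomial" && length(unique(y)) < 2) {
    stop("outcome has no variation")
  }
  # unstratified folds: stratification makes the fold-level deviances of
  # the null model nearly identical, collapsing the standard error the
  # one-SE rule relies on and letting noise terms through the screen
  foldid <- make_folds(y, folds, seed = seed, stratify = FALSE)
  cv <- glmnet::cv.glmnet(design$x, y, family = family, foldid = foldid,
                          standardize = FALSE)
  lam <- if (rule == "1se") cv$lambda.1se else cv$lambda.min
  beta <- stats::coef(cv, s = lam)
  co <- as.matrix(beta)[, 1]
  nz <- co[names(co) != "(Intercept)" & co != 0]
  structure(list(
    selected = names(nz), lambda = lam, coefficients = co,
    nonzero = nz, n = length(y), family = family, rule = rule,
    cvm = data.frame(lambda = cv$lambda, cvm = cv$cvm, cvsd = cv$cvsd),
    dropped = design$dropped
  ), class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("Lasso screen (%s, %s rule, n = %d): %d term(s) selected\n",
              x$family, x$rule, x$n, length(x$selected)))
  if (length(x$selected)) {
    for (s in x$selected) cat(sprintf("  %s  (coef %.3g)\n", s, x$nonzero[[s]]))
  }
  invisible(x)
}
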