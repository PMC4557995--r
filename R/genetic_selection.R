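# Step-down selection of genetic terms over a fixed non-genetic base
# model. Backward elimination under a deviance + k * df criterion, with
# the per-degree-of-freedom penalty k tuned to minimise the
# cross-validated Brier score (CVE) of the resulting model; effect
# estimation as adjusted odds ratios, marginally-standardised relative
# risks, and rank-based AUC.

# --- low-level fitting -----------------------------------------------------

fit_glm_matrix <- function(y, X, family = "binomial", start = NULL) {
  fam <- if (family == "binomial") stats::binomial() else stats::gaussian()
  Xi <- cbind(`(Intercept)` = rep(1, length(y)), X)
  if (!is.null(start)) {
    start <- start[colnames(Xi)]
    start[is.na(start)] <- 0
  }
  fit <- suppressWarnings(stats::glm.fit(Xi, y, family = fam, start = start,
                                         control = list(maxit = 100)))
  fit$x_names <- colnames(Xi)
  fit
}

predict_glm_matrix <- function(fit, Xnew, family = "binomial") {
  co <- fit$coefficients
  co[is.na(co)] <- 0
  eta <- cbind(1, Xnew) %*% co
  if (family == "binomial") expit(as.vector(eta)) else as.vector(eta)
}

# --- cross-validated error -------------------------------------------------

#' Brier score of fixed predicted probabilities
#'
#' Mean squared difference between observed binary outcomes and predicted
#' probabilities. For a constant prediction p against prevalence q this is
#' p^2 (1 - q) + (1 - p)^2 q.
#'
#' @param y Binary outcomes (0/1 or logical).
#' @param p Predicted probabilities (recycled if scalar).
#' @return Mean squared prediction error.
#' @export
brier_score <- function(y, p) {
  y <- as.numeric(y)
  mean((y - p)^2)
}

#' Cross-validated prediction error (CVE)
#'
#' Repeated k-fold cross-validation of a generalized linear model given by
#' a design matrix: within each training fold the model is refit and the
#' held-out squared prediction error recorded. For a binary outcome this
#' is the cross-validated Brier score (mean squared
#' observed-minus-predicted-probability); for a gaussian outcome the CV
#' mean squared error. The result is the mean over repeats and folds of
#' the per-fold mean squared error. Folds are stratified for binary
#' outcomes. A training fold degenerate to a single class is predicted by
#' its shrunken prevalence `(sum(y) + 0.5) / (n + 1)`.
#'
#' @param y Outcome vector (binary 0/1 or numeric).
#' @param x Design matrix of predictors, or `NULL` for an intercept-only
#'   model.
#' @param folds Number of CV folds (>= 2).
#' @param repeats Number of CV repeats.
#' @param seed Integer seed controlling the fold draws.
#' @param family `"binomial"` or `"gaussian"`.
#' @return The cross-validated error (a single number).
#' @export
cve <- function(y, x = NULL, folds = 10, repeats = 5, seed = 1,
                family = "binomial") {
  if (folds < 2) stop("folds must be at least 2")
  y <- as.numeric(y)
  n <- length(y)
  if (!is.null(x)) x <- as.matrix(x)
  per_repeat <- numeric(repeats)
  for (r in seq_len(repeats)) {
    foldid <- make_folds(y, folds, seed = derive_seed(seed, paste0("cv", r)))
    fold_err <- numeric(folds)
    for (f in seq_len(folds)) {
      test <- foldid == f
      ytr <- y[!test]
      if (family == "binomial" && length(unique(ytr)) < 2) {
        p <- rep((sum(ytr) + 0.5) / (length(ytr) + 1), sum(test))
      } else if (is.null(x) || ncol(x) == 0) {
        p <- rep(mean(ytr), sum(test))
      } else {
        fit <- fit_glm_matrix(ytr, x[!test, , drop = FALSE], family)
        p <- predict_glm_matrix(fit, x[test, , drop = FALSE], family)
      }
      fold_err[f] <- mean((y[test] - p)^2)
    }
    per_repeat[r] <- mean(fold_err)
  }
  mean(per_repeat)
}

#' Rank-based area under the ROC curve
#'
#' Probability that a randomly chosen case receives a higher score than a
#' randomly chosen non-case, with ties counted half (the Mann-Whitney
#' form).
#'
#' @param scores Numeric predictions.
#' @param labels Binary outcomes (0/1 or logical).
#' @return AUC in `[0, 1]`, or `NA` (with a warning) for single-class data.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    warning("AUC undefined for single-class data")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# --- candidate construction ------------------------------------------------

#' Build candidate genetic term matrices for selection
#'
#' For each SNP, enters the requested codings as alternative candidate
#' terms: `dominant` (variant carrier), `recessive` (homozygous variant)
#' and `genotypic` (two indicator columns, homozygous wild-type as
#' reference). Codings that are degenerate in the data (zero variance, or
#' a genotype class absent for the genotypic coding) are skipped.
#'
#' @param genotypes Data frame of 0/1/2 genotype columns (no missing
#'   values; restrict rows first).
#' @param snps SNP column names to use; default all.
#' @param codings Character vector out of `"dominant"`, `"recessive"`,
#'   `"genotypic"`, `"additive"`.
#' @return Named list of candidate matrices (rows aligned to
#'   `genotypes`), names like `"rs6853 (carrier)"`.
#' @export
build_genetic_candidates <- function(genotypes,
                                     snps = names(genotypes),
                                     codings = c("dominant", "recessive",
                                                 "genotypic")) {
  genotypes <- as.data.frame(genotypes)
  out <- list()
  for (s in snps) {
    g <- genotypes[[s]]
    if (anyNA(g)) stop("candidate construction requires complete genotypes")
    if ("dominant" %in% codings) {
      v <- as.numeric(g >= 1)
      if (stats::sd(v) > 0) out[[paste0(s, " (carrier)")]] <- matrix(v,
        dimnames = list(NULL, paste0(s, " (carrier)")))
    }
    if ("recessive" %in% codings) {
      v <- as.numeric(g == 2)
      if (stats::sd(v) > 0) out[[paste0(s, " (hom)")]] <- matrix(v,
        dimnames = list(NULL, paste0(s, " (hom)")))
    }
    if ("additive" %in% codings) {
      v <- as.numeric(g)
      if (stats::sd(v) > 0) out[[paste0(s, " (additive)")]] <- matrix(v,
        dimnames = list(NULL, paste0(s, " (additive)")))
    }
    if ("genotypic" %in% codings) {
      if (all(0:2 %in% g)) {
        m <- cbind(as.numeric(g == 1), as.numeric(g == 2))
        colnames(m) <- paste0(s, c(" (het)", " (homvar)"))
        out[[paste0(s, " (genotypic)")]] <- m
      }
    }
  }
  out
}

# --- step-down selection ---------------------------------------------------

set_key <- function(nms) paste(c("m", sort(nms)), collapse = "|")

#' Step-down genetic model selection penalised by cross-validation error
#'
#' Starting from the fixed non-genetic base model plus all candidate
#' genetic terms, repeatedly removes the genetic term whose removal most
#' decreases the criterion `deviance + k * df` (df = number of estimated
#' coefficients), stopping when no removal decreases it; base terms are
#' never removed. The final model at each penalty `k` in the grid is
#' evaluated by repeated cross-validated prediction error ([cve()]) under
#' folds shared across all evaluations, and the model with minimal CVE is
#' returned (ties in `k` broken toward the larger, more parsimonious,
#' penalty). The result records whether the selected model's CVE beats the
#' base model's.
#'
#' @param y Outcome (binary 0/1 or numeric).
#' @param base_x Matrix of fixed base-model columns (or `NULL`).
#' @param candidates Named list of candidate term matrices
#'   ([build_genetic_candidates()]), rows aligned with `y`.
#' @param k_grid Penalties per degree of freedom to scan.
#' @param folds,repeats,seed Cross-validation settings passed to [cve()].
#' @param family `"binomial"` or `"gaussian"` (continuous-response mode).
#' @return Object of class `"stepdown_result"`: `selected` (term names),
#'   `k`, `cve`, `cve_base`, `auc` (binomial only), `fit`, `path` of
#'   per-penalty results, plus the data needed for [estimate_effects()].
#' @export
stepdown_select <- function(y, base_x, candidates,
                            k_grid = seq(0, 10, by = 0.1),
                            folds = 10, repeats = 5, seed = 1,
                            family = "binomial") {
  y <- as.numeric(y)
  n <- length(y)
  if (!is.null(base_x)) {
    base_x <- as.matrix(base_x)
    stopifnot(nrow(base_x) == n)
  }
  for (m in candidates) stopifnot(nrow(m) == n)

  model_matrix <- function(set) {
    cbind(base_x, do.call(cbind, unname(candidates[set])))
  }
  # model degrees of freedom: declared coefficients (intercept + base +
  # term columns). Counting columns rather than fitted rank lets the
  # penalty eliminate a coding made redundant by an alternative coding of
  # the same SNP, whose removal leaves deviance (and rank) unchanged.
  term_df <- vapply(candidates, ncol, integer(1))
  df_base <- 1 + (if (is.null(base_x)) 0 else ncol(base_x))
  df_of <- function(set) df_base + sum(term_df[set])

  # One "node" per visited term set: the set's deviance, the fitted
  # coefficients (warm starts for its children), and the deviance of every
  # single-term removal. The per-penalty walk below then costs only
  # arithmetic on cached values.
  nodes <- new.env(parent = emptyenv())
  get_node <- function(set, warm = NULL) {
    key <- set_key(set)
    hit <- get0(key, envir = nodes)
    if (!is.null(hit)) return(hit)
    fit <- fit_glm_matrix(y, model_matrix(set), family, start = warm)
    co <- stats::setNames(fit$coefficients, fit$x_names)
    dev_wo <- vapply(set, function(t) {
      fit_glm_matrix(y, model_matrix(setdiff(set, t)), family,
                     start = co)$deviance
    }, numeric(1))
    node <- list(set = set, dev = fit$deviance, coef = co, dev_wo = dev_wo)
    assign(key, node, envir = nodes)
    node
  }

  greedy_final_set <- function(k) {
    node <- get_node(names(candidates))
    repeat {
      set <- node$set
      if (!length(set)) return(set)
      crit <- node$dev + k * df_of(set)
      cand_crit <- node$dev_wo + k * (df_of(set) - term_df[set])
      best <- which.min(cand_crit)
      # tolerance above IRLS convergence jitter, so a purely redundant
      # term is not "removed" at k = 0 by numerical noise
      if (cand_crit[best] < crit - 1e-4) {
        node <- get_node(setdiff(set, set[best]), warm = node$coef)
      } else {
        return(set)
      }
    }
  }

  cve_seed <- derive_seed(seed, "cve")
  cve_cache <- new.env(parent = emptyenv())
  cve_of_set <- function(set) {
    key <- set_key(set)
    hit <- get0(key, envir = cve_cache)
    if (!is.null(hit)) return(hit)
    val <- cve(y, model_matrix(set), folds = folds, repeats = repeats,
               seed = cve_seed, family = family)
    assign(key, val, envir = cve_cache)
    val
  }

  cve_base <- cve(y, base_x, folds = folds, repeats = repeats,
                  seed = cve_seed, family = family)

  path <- data.frame(k = k_grid, n_terms = NA_integer_, cve = NA_real_)
  sets <- vector("list", length(k_grid))
  best <- NULL
  for (i in seq_along(k_grid)) {
    k <- k_grid[i]
    set <- greedy_final_set(k)
    sets[[i]] <- set
    path$n_terms[i] <- length(set)
    path$cve[i] <- cve_of_set(set)
    if (is.null(best) || path$cve[i] <= best$cve) {
      best <- list(k = k, set = set, cve = path$cve[i])
    }
  }
  # the base model always competes: genetic terms are only returned when
  # their model's CVE beats the base model's (ties resolve to the base)
  if (cve_base <= best$cve && length(best$set)) {
    best <- list(k = max(k_grid), set = character(0), cve = cve_base)
  }

  final_x <- model_matrix(best$set)
  fit <- fit_glm_matrix(y, final_x, family)
  fitted_p <- predict_glm_matrix(fit, final_x, family)
  structure(list(
    selected = best$set, k = best$k, cve = best$cve, cve_base = cve_base,
    better_than_base = best$cve < cve_base,
    auc = if (family == "binomial") roc_auc(fitted_p, y) else NA_real_,
    coefficients = stats::setNames(fit$coefficients, fit$x_names),
    path = path, family = family, n = n,
    folds = folds, repeats = repeats, seed = seed,
    y = y, base_x = base_x, candidates = candidates
  ), class = "stepdown_result")
}

#' @export
print.stepdown_result <- function(x, ...) {
  cat(sprintf("Step-down selection (%s, n = %d)\n", x$family, x$n))
  cat(sprintf("  optimal k = %.3g; CVE = %.4g (base model %.4g)%s\n",
              x$k, x$cve, x$cve_base,
              if (x$better_than_base) " [beats base]" else ""))
  if (!is.na(x$auc)) cat(sprintf("  AUC = %.3g\n", x$auc))
  if (length(x$selected)) {
    cat("  genetic terms:", paste(x$selected, collapse = ", "), "\n")
  } else {
    cat("  no genetic terms retained\n")
  }
  invisible(x)
}

# --- effect estimation -----------------------------------------------------

#' Effect estimates for a fitted selection model
#'
#' For each single-column term of the final model: the adjusted odds ratio
#' (exponentiated coefficient) with Wald 95% confidence interval, a
#' nested-model likelihood-ratio p-value from dropping the term, and — for
#' binary terms under a binomial family — the relative risk by marginal
#' standardisation (ratio of mean predicted risk over all subjects with
#' the term set to exposed versus reference) with a percentile bootstrap
#' confidence interval.
#'
#' @param result A [stepdown_select()] result (or a compatible list with
#'   `y`, `base_x`, `candidates`, `selected`, `family`).
#' @param terms Term names to report; default the selected genetic terms.
#' @param bootstrap_reps Bootstrap resamples for the RR interval.
#' @param seed Integer seed for the bootstrap.
#' @param conf_level Confidence level.
#' @return Data frame with one row per reported coefficient: `term`,
#'   `odds_ratio`, `or_lower`, `or_upper`, `p_nested`, `relative_risk`,
#'   `rr_lower`, `rr_upper`.
#' @export
estimate_effects <- function(result, terms = result$selected,
                             bootstrap_reps = 200, seed = 1,
                             conf_level = 0.95) {
  y <- result$y
  family <- result$family
  base_x <- result$base_x
  sel_x <- do.call(cbind, unname(result$candidates[result$selected]))
  X <- cbind(base_x, sel_x)
  df <- as.data.frame(X, check.names = FALSE)
  nm <- colnames(X)
  df$.y <- y
  fam <- if (family == "binomial") stats::binomial() else stats::gaussian()
  form <- stats::as.formula(paste(".y ~",
    paste(sprintf("`%s`", nm), collapse = " + ")))
  fit <- stats::glm(form, data = df, family = fam)
  sm <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - conf_level) / 2)

  marginal_rr <- function(fit, df, col) {
    d1 <- df; d1[[col]] <- 1
    d0 <- df; d0[[col]] <- 0
    # aliased columns carry zero weight in prediction; the rank-deficiency
    # warning is expected when alternative codings of one SNP co-occur
    suppressWarnings(
      mean(stats::predict(fit, newdata = d1, type = "response")) /
        mean(stats::predict(fit, newdata = d0, type = "response")))
  }

  rows <- list()
  for (term in terms) {
    cols <- colnames(result$candidates[[term]]) %||% term
    for (col in cols) {
      rn <- paste0("`", col, "`")
      if (!rn %in% rownames(sm)) rn <- col
      if (!rn %in% rownames(sm) || is.na(fit$coefficients[[rn]])) next
      est <- sm[rn, "Estimate"]; se <- sm[rn, "Std. Error"]
      # nested-model LRT: drop every column of this term
      drop_cols <- setdiff(nm, cols)
      form0 <- if (length(drop_cols)) {
        stats::as.formula(paste(".y ~",
          paste(sprintf("`%s`", drop_cols), collapse = " + ")))
      } else stats::as.formula(".y ~ 1")
      fit0 <- stats::glm(form0, data = df, family = fam)
      p_lrt <- stats::pchisq(fit0$deviance - fit$deviance,
                             df = length(cols), lower.tail = FALSE)
      is_binary <- all(df[[col]] %in% 0:1)
      rr <- rr_lo <- rr_hi <- NA_real_
      if (family == "binomial" && is_binary) {
        rr <- marginal_rr(fit, df, col)
        if (bootstrap_reps > 0) {
          boots <- with_seed(derive_seed(seed, paste0("rr", col)), {
            vapply(seq_len(bootstrap_reps), function(b) {
              idx <- sample.int(nrow(df), replace = TRUE)
              db <- df[idx, , drop = FALSE]
              fb <- suppressWarnings(stats::glm(form, data = db, family = fam))
              marginal_rr(fb, db, col)
            }, numeric(1))
          })
          qs <- stats::quantile(boots, c((1 - conf_level) / 2,
                                         1 - (1 - conf_level) / 2),
                                na.rm = TRUE, names = FALSE)
          rr_lo <- qs[1]; rr_hi <- qs[2]
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        term = col,
        odds_ratio = exp(est),
        or_lower = exp(est - z * se), or_upper = exp(est + z * se),
        p_nested = p_lrt,
        relative_risk = rr, rr_lower = rr_lo, rr_upper = rr_hi)
    }
  }
  if (!length(rows)) {
    return(data.frame(term = character(0), odds_ratio = numeric(0),
                      or_lower = numeric(0), or_upper = numeric(0),
                      p_nested = numeric(0), relative_risk = numeric(0),
                      rr_lower = numeric(0), rr_upper = numeric(0)))
  }
  do.call(rbind, rows)
}

# --- data assembly for a cohort --------------------------------------------

#' Assemble selection inputs for one outcome from a cohort
#'
#' Complete-case rows for the outcome, the base covariate columns (as
#' selected by the lasso screen, on the standardized transformed scale)
#' and all candidate SNP genotypes.
#'
#' @param cohort Cohort with phenotype columns.
#' @param outcome Outcome column name (binary phenotype or a continuous
#'   column such as `delivery_rate`).
#' @param base_terms Character vector of base-model column names from the
#'   screen design (may be empty).
#' @param snps SNP columns to enter as candidates.
#' @param codings Candidate codings per SNP (see
#'   [build_genetic_candidates()]).
#' @return List with `y`, `base_x`, `candidates`, `rows` (cohort row
#'   indices used) and `family`.
#' @export
stepdown_data <- function(cohort, outcome, base_terms = character(0),
                          snps = names(cohort_genotypes(cohort)),
                          codings = c("dominant", "recessive", "genotypic")) {
  design <- build_design(cohort, outcome)
  g <- cohort_genotypes(cohort)[design$rows, snps, drop = FALSE]
  ok <- stats::complete.cases(g)
  rows <- design$rows[ok]
  y <- design$y[ok]
  base_x <- if (length(base_terms)) {
    missing_terms <- setdiff(base_terms, colnames(design$x))
    if (length(missing_terms)) {
      stop("base terms not in screen design: ",
           paste(missing_terms, collapse = ", "))
    }
    design$x[ok, base_terms, drop = FALSE]
  } else NULL
  candidates <- build_genetic_candidates(g[ok, , drop = FALSE],
                                         codings = codings)
  family <- if (all(y %in% 0:1)) "binomial" else "gaussian"
  list(y = y, base_x = base_x, candidates = candidates, rows = rows,
       family = family)
}
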