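# Contingency-table statistics: Fisher's exact test, crude odds ratios and
# relative risks with Woolf confidence intervals, the adverse-event
# co-incidence matrix, and chi-squared independence checks.

as_2x2 <- function(a, b, c, d) {
  t <- c(a = a, b = b, c = c, d = d)
  if (any(t < 0) || any(t != round(t))) stop("cell counts must be non-negative integers")
  if (sum(t) < 1) stop("table total must be at least 1")
  t
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the probability-mass rule: the sum of
#' hypergeometric probabilities, at fixed margins, of all tables at least
#' as improbable as the one observed.
#'
#' @param a,b,c,d Cell counts: exposed-case, exposed-noncase,
#'   unexposed-case, unexposed-noncase.
#' @return Two-sided p-value.
#' @examples
#' fisher_exact(3, 1, 1, 3)  # 34/70
#' @export
fisher_exact <- function(a, b, c, d) {
  as_2x2(a, b, c, d)
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) return(1)
  m <- matrix(c(a, c, b, d), 2)
  stats::fisher.test(m)$p.value
}

#' Crude association measures for a 2x2 table
#'
#' Sample odds ratio `ad/bc` with a Woolf (log-normal) 95% confidence
#' interval, per-arm incidences, the crude relative risk, and both exact
#' and chi-squared p-values. When a zero cell makes the odds ratio
#' degenerate, the Haldane-Anscombe 0.5 continuity correction is applied
#' to the odds-ratio estimate and interval, and the result is flagged.
#'
#' @inheritParams fisher_exact
#' @param conf_level Confidence level for the Woolf interval.
#' @return An object of class `"assoc_2x2"`: a list with `odds_ratio`,
#'   `or_ci`, `relative_risk`, `incidence` (length-2: exposed, unexposed),
#'   `p_exact`, `p_chisq`, `corrected` (logical: Haldane-Anscombe applied)
#'   and the cell counts.
#' @examples
#' odds_ratio_ci(11, 100, 69, 256)  # incidences ~10% vs ~21%, RR ~0.47
#' @export
odds_ratio_ci <- function(a, b, c, d, conf_level = 0.95) {
  as_2x2(a, b, c, d)
  corrected <- any(c(a, b, c, d) == 0)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  cc <- if (corrected) 0.5 else 0
  or <- ((a + cc) * (d + cc)) / ((b + cc) * (c + cc))
  se <- sqrt(1 / (a + cc) + 1 / (b + cc) + 1 / (c + cc) + 1 / (d + cc))
  inc <- c(exposed = if (a + b > 0) a / (a + b) else NA_real_,
           unexposed = if (c + d > 0) c / (c + d) else NA_real_)
  rr <- inc[["exposed"]] / inc[["unexposed"]]
  p_chi <- if (all(rowSums(matrix(c(a, b, c, d), 2, byrow = TRUE)) > 0) &&
               all(c(a + c, b + d) > 0)) {
    suppressWarnings(stats::chisq.test(matrix(c(a, c, b, d), 2),
                                       correct = FALSE)$p.value)
  } else NA_real_
  structure(list(
    counts = c(a = a, b = b, c = c, d = d),
    odds_ratio = or,
    or_ci = c(lower = or * exp(-z * se), upper = or * exp(z * se)),
    relative_risk = rr,
    incidence = inc,
    p_exact = fisher_exact(a, b, c, d),
    p_chisq = p_chi,
    corrected = corrected
  ), class = "assoc_2x2")
}

#' @export
print.assoc_2x2 <- function(x, ...) {
  cat(sprintf("2x2 association: OR %.3g (95%% CI %.3g-%.3g)%s\n",
              x$odds_ratio, x$or_ci[1], x$or_ci[2],
              if (x$corrected) " [Haldane-Anscombe corrected]" else ""))
  cat(sprintf("  incidence %.1f%% (exposed) vs %.1f%% (unexposed); RR %.3g\n",
              100 * x$incidence[1], 100 * x$incidence[2], x$relative_risk))
  cat(sprintf("  Fisher exact p = %.3g; chi-squared p = %.3g\n",
              x$p_exact, x$p_chisq))
  invisible(x)
}

#' Pairwise co-incidence matrix of adverse-event flags
#'
#' For each pair of binary symptom flags, computes the crude odds ratio
#' with Woolf confidence interval and Fisher's exact p-value over
#' complete-case patients for that pair, in a lower-triangle layout.
#'
#' @param flags Data frame or named list of logical vectors (one per
#'   symptom), all the same length; NA allowed.
#' @return A data frame with one row per symptom pair: `symptom_a`,
#'   `symptom_b`, `n`, `odds_ratio`, `or_lower`, `or_upper`, `p_exact`,
#'   `degenerate` (TRUE when a flag is constant so the pair is undefined).
#' @export
coincidence_matrix <- function(flags) {
  flags <- as.data.frame(flags)
  if (ncol(flags) < 2) stop("need at least 2 symptom flags")
  usable <- vapply(flags, function(f) {
    f <- f[!is.na(f)]
    length(unique(f)) == 2
  }, logical(1))
  if (sum(usable) < 2) stop("need at least 2 symptoms with both levels present")
  nm <- names(flags)
  out <- list()
  for (i in seq_along(nm)[-1]) {
    for (j in seq_len(i - 1)) {
      ok <- !is.na(flags[[i]]) & !is.na(flags[[j]])
      fi <- flags[[i]][ok]; fj <- flags[[j]][ok]
      degenerate <- length(unique(fi)) < 2 || length(unique(fj)) < 2
      if (degenerate) {
        row <- data.frame(symptom_a = nm[i], symptom_b = nm[j], n = sum(ok),
                          odds_ratio = NA_real_, or_lower = NA_real_,
                          or_upper = NA_real_, p_exact = NA_real_,
                          degenerate = TRUE)
      } else {
        a <- sum(fi & fj); b <- sum(!fi & fj)
        c_ <- sum(fi & !fj); d <- sum(!fi & !fj)
        res <- odds_ratio_ci(a, b, c_, d)
        row <- data.frame(symptom_a = nm[i], symptom_b = nm[j], n = sum(ok),
                          odds_ratio = res$odds_ratio,
                          or_lower = res$or_ci[[1]], or_upper = res$or_ci[[2]],
                          p_exact = res$p_exact, degenerate = FALSE)
      }
      out[[length(out) + 1]] <- row
    }
  }
  do.call(rbind, out)
}

#' Chi-squared test of outcome independence across groups
#'
#' Pearson chi-squared test (no continuity correction) of a binary outcome
#' across G groups, on the G x 2 contingency table with G - 1 degrees of
#' freedom. Used e.g. to confirm the absence of outcome association with
#' ancestry subgroup before pooling subgroups in association analyses.
#'
#' @param groups Group labels (factor or vector coercible to factor).
#' @param flags Logical outcome per subject (NA dropped pairwise).
#' @return List with `chi2`, `df`, `p_value`, `table` and `dropped_groups`
#'   (labels of empty groups removed before testing).
#' @export
chisq_independence <- function(groups, flags) {
  ok <- !is.na(groups) & !is.na(flags)
  groups <- factor(groups[ok])
  flags <- flags[ok]
  tab <- table(groups, flags)
  dropped <- rownames(tab)[rowSums(tab) == 0]
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2) stop("need at least 2 non-empty groups")
  if (ncol(tab) < 2) stop("outcome has a single level")
  fit <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(fit$statistic), df = unname(fit$parameter),
       p_value = fit$p.value, table = tab, dropped_groups = dropped)
}
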