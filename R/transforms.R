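# Box-Cox transformation machinery and the fixed covariate transform
# registry used throughout the analysis.

#' Box-Cox power transformation
#'
#' Computes `(x^lambda - 1) / lambda` for `lambda != 0` and `log(x)` for
#' `lambda = 0`; the two branches join continuously at `lambda = 0`.
#'
#' @param x Positive numeric vector.
#' @param lam Box-Cox exponent (a single finite number).
#' @return Numeric vector of transformed values.
#' @examples
#' apply_boxcox(3, 2)   # (9 - 1) / 2 = 4
#' apply_boxcox(exp(1), 0)  # 1
#' @export
apply_boxcox <- function(x, lam) {
  if (!is.numeric(x)) stop("x must be numeric")
  if (any(x <= 0, na.rm = TRUE)) {
    stop("Box-Cox transformation requires strictly positive values")
  }
  if (length(lam) != 1 || !is.finite(lam)) stop("lam must be a single finite number")
  if (lam == 0) log(x) else (x^lam - 1) / lam
}

# Profile log-likelihood of the normal model for Box-Cox transformed data,
# including the Jacobian term (lam - 1) * sum(log x).
boxcox_loglik <- function(x, lam) {
  n <- length(x)
  z <- apply_boxcox(x, lam)
  s2 <- stats::var(z) * (n - 1) / n
  -n / 2 * log(s2) + (lam - 1) * sum(log(x))
}

#' Select a Box-Cox exponent by profile likelihood
#'
#' Maximises the Box-Cox profile log-likelihood (normal model on the
#' transformed scale, with the Jacobian term) over a grid of exponents.
#'
#' @param values Positive numeric vector (at least 10 values).
#' @param grid Candidate exponents; default `seq(-3, 3, by = 0.01)`.
#' @return The grid value maximising the profile log-likelihood.
#' @export
select_lambda <- function(values, grid = seq(-3, 3, by = 0.01)) {
  values <- values[!is.na(values)]
  if (length(values) < 10) stop("need at least 10 positive values")
  if (any(values <= 0)) stop("Box-Cox selection requires strictly positive values")
  ll <- vapply(grid, function(l) boxcox_loglik(values, l), numeric(1))
  grid[which.max(ll)]
}

# Fixed per-covariate transforms: continuous clinical covariates are mapped
# to an approximately normal scale before any regression sees them.
.transform_table <- list(
  age                  = list(kind = "boxcox", lam = 2),
  bmi                  = list(kind = "log10"),
  albumin              = list(kind = "boxcox", lam = 0.75),
  creatinine_clearance = list(kind = "boxcox", lam = 0.25),
  time_on_opioids_days = list(kind = "log10"),
  serum_fentanyl_nM    = list(kind = "log10"),
  delivery_rate        = list(kind = "log10"),
  karnofsky            = list(kind = "sqrt")
)

#' The fixed covariate transform registry
#'
#' Returns the transform applied to a named clinical covariate before
#' modelling: age is squared (Box-Cox exponent 2), BMI, time on opioids and
#' serum fentanyl concentration are log10-transformed, serum albumin uses
#' exponent 0.75, creatinine clearance exponent 0.25, and the Karnofsky
#' performance score is square-root transformed. Every other covariate is
#' passed through unchanged.
#'
#' @param covariate_name Covariate name (one of the cohort column names).
#' @param known_names Optional character vector of valid covariate names;
#'   lookup of a name outside this set is an error. Defaults to the cohort
#'   covariate names plus the registry keys.
#' @return A list with elements `kind` (one of `"boxcox"`, `"log10"`,
#'   `"sqrt"`, `"square"`, `"identity"`) and, for `kind = "boxcox"`, `lam`.
#' @export
registry_transform <- function(covariate_name,
                               known_names = cohort_covariate_names()) {
  if (!covariate_name %in% union(known_names, names(.transform_table))) {
    stop(sprintf("unknown covariate '%s'", covariate_name))
  }
  tr <- .transform_table[[covariate_name]]
  if (is.null(tr)) tr <- list(kind = "identity")
  if (identical(tr, list(kind = "boxcox", lam = 2))) tr$kind_alias <- "square"
  tr
}

#' Apply a registry transform to a numeric vector
#'
#' @param spec Transform spec as returned by [registry_transform()].
#' @param x Numeric vector.
#' @param shift_zeros If `TRUE`, values equal to zero are shifted up by half
#'   the smallest positive observed value before log or Box-Cox transforms
#'   (degenerate zeros otherwise have no image under these transforms).
#' @return Transformed numeric vector.
#' @export
apply_transform <- function(spec, x, shift_zeros = TRUE) {
  if (spec$kind %in% c("log10", "boxcox") && shift_zeros &&
      any(x == 0, na.rm = TRUE) && any(x > 0, na.rm = TRUE)) {
    x[!is.na(x) & x == 0] <- min(x[!is.na(x) & x > 0]) / 2
  }
  switch(spec$kind,
    identity = x,
    log10    = log10(x),
    sqrt     = sqrt(x),
    square   = x^2,
    boxcox   = apply_boxcox(x, spec$lam),
    stop(sprintf("unknown transform kind '%s'", spec$kind))
  )
}

#' Serialise the transform registry
#'
#' @return Named list of transform specs for all registered covariates,
#'   suitable for writing into a pipeline configuration file.
#' @export
transform_registry <- function() .transform_table
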