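# Synthetic cohort generator. Emulates the data structure the analysis
# assumes for a transdermal-fentanyl cancer-pain cohort: clinical covariate
# marginals, candidate-SNP genotypes under Hardy-Weinberg equilibrium with
# within-gene LD blocks, logistic outcome latents on transformed
# covariates and genetic codings, and symptom-instrument scores sampled
# consistently with the outcome latents so that phenotype classification
# exactly recovers them.

#' Names of the cohort's non-genetic covariate columns
#'
#' @param candidates_only If `TRUE` (default `FALSE`), restrict to the
#'   covariates entered as candidates in the non-genetic lasso screen
#'   (fentanyl patch delivery rate and ancestry subgroup are summarised
#'   but not screened).
#' @return Character vector of column names.
#' @export
cohort_covariate_names <- function(candidates_only = FALSE) {
  screened <- c("age", "sex", "centre_country", "bmi", "albumin", "crp_gt40",
                "creatinine_clearance", "kidney_disease",
                "time_on_opioids_days", "serum_fentanyl_nM",
                "breakthrough_opioid", "karnofsky")
  if (candidates_only) screened
  else c(screened, "delivery_rate", "ancestry_subgroup")
}

# ---------------------------------------------------------------------------
# Default specifications

#' Default candidate-SNP panel
#'
#' The 31-SNP, 19-gene innate-immune / opioid-signalling candidate panel
#' (ABCB1 reduced to its three phenotype-associated tag SNPs, which stand
#' in near-complete LD with the rest of the gene). Within-gene LD is
#' specified through haplotype frequencies for multi-SNP genes; allele
#' frequencies are plausible defaults, not published values, except the
#' MYD88 rs6853 frequency which is set so the variant-carrier fraction is
#' about 0.255. All frequencies are configurable.
#'
#' @return List with `snp_specs` (one spec per SNP: `snp_id`, `gene`,
#'   `maf`, `block_id`) and `ld_blocks` (per block: `snps`, `hap_freqs`
#'   named by allele string in SNP order).
#' @export
default_snp_panel <- function() {
  blocks <- list(
    TLR4 = list(
      snps = c("rs4986790", "rs4986791"),
      hap_freqs = c("00" = 0.940, "11" = 0.055, "10" = 0.005)),
    IL1B = list(
      snps = c("rs1143627", "rs1143634", "rs16944"),
      hap_freqs = c("000" = 0.38, "011" = 0.02, "001" = 0.35,
                    "110" = 0.05, "100" = 0.20)),
    CASP1 = list(
      snps = c("rs554344", "rs580253"),
      hap_freqs = c("00" = 0.60, "11" = 0.36, "01" = 0.02, "10" = 0.02)),
    IL10 = list(
      snps = c("rs1800871", "rs1800896"),
      hap_freqs = c("00" = 0.45, "01" = 0.30, "10" = 0.20, "11" = 0.05)),
    TGFB1 = list(
      snps = c("rs11466314", "rs1800469"),
      hap_freqs = c("00" = 0.58, "01" = 0.31, "10" = 0.08, "11" = 0.03)),
    ARRB2 = list(
      snps = c("rs3786047", "rs1045280", "rs2271167", "rs2036657"),
      hap_freqs = c("0000" = 0.35, "1111" = 0.20, "1100" = 0.15,
                    "0011" = 0.10, "1000" = 0.10, "0100" = 0.05,
                    "0010" = 0.05)),
    STAT6 = list(
      snps = c("rs3024971", "rs167769"),
      hap_freqs = c("00" = 0.55, "01" = 0.28, "10" = 0.12, "11" = 0.05)),
    ABCB1 = list(
      snps = c("rs1045642", "rs2235013", "rs1128503"),
      hap_freqs = c("000" = 0.52, "111" = 0.44, "100" = 0.02, "011" = 0.02))
  )
  independent <- list(
    list(snp_id = "rs3804100",  gene = "TLR2",  maf = 0.07),
    list(snp_id = "rs11466004", gene = "LY96",  maf = 0.05),
    list(snp_id = "rs6853",     gene = "MYD88", maf = 0.137),
    list(snp_id = "rs10499563", gene = "IL6",   maf = 0.25),
    list(snp_id = "rs8192284",  gene = "IL6R",  maf = 0.40),
    list(snp_id = "rs2069762",  gene = "IL2",   maf = 0.28),
    list(snp_id = "rs2794521",  gene = "CRP",   maf = 0.30),
    list(snp_id = "rs1800629",  gene = "TNF",   maf = 0.16),
    list(snp_id = "rs6265",     gene = "BDNF",  maf = 0.19),
    list(snp_id = "rs4680",     gene = "COMT",  maf = 0.48),
    list(snp_id = "rs1799971",  gene = "OPRM1", maf = 0.12)
  )
  specs <- lapply(independent, function(s) { s$block_id <- NA_character_; s })
  for (bid in names(blocks)) {
    b <- blocks[[bid]]
    mafs <- block_implied_mafs(b$hap_freqs, length(b$snps))
    for (i in seq_along(b$snps)) {
      specs[[length(specs) + 1]] <- list(snp_id = b$snps[i], gene = bid,
                                         maf = mafs[i], block_id = bid)
    }
  }
  list(snp_specs = specs, ld_blocks = blocks)
}

# Per-SNP variant allele frequencies implied by block haplotype frequencies.
block_implied_mafs <- function(hap_freqs, n_snps) {
  alle <- do.call(rbind, lapply(names(hap_freqs), function(h) {
    as.integer(strsplit(h, "")[[1]])
  }))
  if (ncol(alle) != n_snps) stop("haplotype labels do not match block size")
  as.vector(crossprod(alle, hap_freqs))
}

#' Default clinical covariate specifications
#'
#' Marginal distributions matched to the study population's summary
#' statistics (median, SD, range, or category counts): truncated normals
#' for roughly symmetric covariates, truncated log-normals for
#' right-skewed ones, category counts for discrete covariates.
#'
#' @return Named list of per-covariate specs.
#' @export
default_covariate_specs <- function() {
  list(
    age = list(type = "truncnorm", median = 64, sd = 12, range = c(24, 88)),
    sex = list(type = "categorical",
               levels = c("male", "female"), counts = c(218, 250)),
    centre_country = list(type = "categorical",
      levels = c("Switzerland", "Germany", "Denmark", "Finland",
                 "United Kingdom", "Greece", "Iceland", "Italy",
                 "Lithuania", "Norway", "Sweden"),
      counts = c(19, 109, 1, 7, 13, 3, 45, 148, 38, 71, 14)),
    bmi = list(type = "truncnorm", median = 23, sd = 5, range = c(9, 41)),
    albumin = list(type = "truncnorm", median = 33, sd = 7, range = c(11, 67)),
    crp_gt40 = list(type = "binary", p = 203 / 467),
    creatinine_clearance = list(type = "lognorm", median = 84, sd = 45,
                                range = c(13, 308)),
    kidney_disease = list(type = "binary", p = 29 / 468),
    time_on_opioids_days = list(type = "lognorm", median = 52, sd = 272,
                                range = c(2, 2332)),
    delivery_rate = list(type = "lognorm", median = 50, sd = 53,
                         range = c(12.5, 400)),
    serum_fentanyl_nM = list(type = "lognorm", median = 5.6, sd = 11.1,
                             range = c(0.09, 144.5)),
    breakthrough_opioid = list(type = "binary", p = 159 / 468),
    karnofsky = list(type = "karnofsky", median = 60, sd = 17,
                     range = c(20, 100)),
    ancestry_subgroup = list(type = "categorical",
                             levels = c("1", "2", "3", "4"),
                             counts = c(45, 30, 15, 10))
  )
}

#' Default per-outcome logistic models
#'
#' Outcome latents are drawn from logistic models on registry-transformed
#' covariates and genetic codings, with intercepts calibrated at
#' generation time so mean risk equals the target prevalence. Cognitive
#' dysfunction uses the published adjusted odds ratios (squared age
#' 1.00037 per unit, square-root Karnofsky 0.63 per unit, MYD88 rs6853
#' variant carrier 0.38); pain control has no systematic predictors; the
#' sickness-response and adverse-event models use plausible effect sizes
#' for the predictors reported for those outcomes (no coefficients were
#' published for them).
#'
#' @return Named list of outcome model specs (`prevalence`, `terms`).
#' @export
default_outcome_models <- function() {
  list(
    pain_control = list(prevalence = 210 / 430, terms = list()),
    cognitive_dysfunction = list(
      prevalence = 81 / 438,
      terms = list(
        list(var = "age", beta = log(1.00037)),
        list(var = "karnofsky", beta = log(0.63)),
        list(snp = "rs6853", coding = "dominant", beta = log(0.38))
      )),
    sickness_response = list(
      prevalence = 148 / 418,
      terms = list(
        list(var = "breakthrough_opioid", beta = log(1.8)),
        list(var = "sex", level = "male", beta = log(0.60)),
        list(var = "centre_country", level = "Italy", beta = log(0.55))
      )),
    opioid_ae_complaint = list(
      prevalence = 329 / 430,
      terms = list(
        list(var = "breakthrough_opioid", beta = log(1.8))
      ))
  )
}

# Instrument dichotomisation rates used for conditional sampling, from the
# cohort's marginal high-symptom fractions.
default_instrument_rates <- function() {
  c(nausea = 89 / 425, tired = 249 / 424, depressed = 135 / 421,
    constipation = 178 / 422)
}

# Missing-completely-at-random rates per field, matched to the per-field
# analysable n out of 468.
default_missingness <- function() {
  c(bpi_average_pain = 38 / 468, mmse = 30 / 468,
    eortc_nausea_vomiting = 43 / 468, eortc_constipation = 46 / 468,
    eortc_tired_item = 44 / 468, eortc_depressed_item = 47 / 468,
    bmi = 8 / 468, albumin = 23 / 468, crp_gt40 = 1 / 468,
    creatinine_clearance = 9 / 468, time_on_opioids_days = 30 / 468,
    karnofsky = 1 / 468, genotype = 0.005)
}

#' Build a cohort-generator configuration
#'
#' @param n_patients Number of patients to simulate.
#' @param seed Integer seed (all generator randomness flows from it).
#' @param covariate_specs Per-covariate distribution specs
#'   ([default_covariate_specs()]).
#' @param snp_panel SNP panel with LD blocks ([default_snp_panel()]).
#' @param outcome_models Per-outcome logistic models
#'   ([default_outcome_models()]).
#' @param missingness_rates Named per-field missing-completely-at-random
#'   probabilities in `[0, 1)` ([default_missingness()]).
#' @param instrument_rates Marginal high-symptom rates used when sampling
#'   instrument indicators conditional on outcome latents.
#' @return List of class `"cohort_config"`.
#' @export
cohort_config <- function(n_patients = 468, seed = 1,
                          covariate_specs = default_covariate_specs(),
                          snp_panel = default_snp_panel(),
                          outcome_models = default_outcome_models(),
                          missingness_rates = default_missingness(),
                          instrument_rates = default_instrument_rates()) {
  config <- structure(list(
    n_patients = n_patients, seed = seed,
    covariate_specs = covariate_specs,
    snp_specs = snp_panel$snp_specs, ld_blocks = snp_panel$ld_blocks,
    outcome_models = outcome_models,
    missingness_rates = missingness_rates,
    instrument_rates = instrument_rates
  ), class = "cohort_config")
  validate_cohort_config(config)
  config
}

validate_cohort_config <- function(config) {
  if (!is.numeric(config$n_patients) || length(config$n_patients) != 1 ||
      config$n_patients < 1 || config$n_patients != round(config$n_patients)) {
    stop_config("n_patients", "must be a positive integer")
  }
  snp_ids <- vapply(config$snp_specs, `[[`, character(1), "snp_id")
  if (anyDuplicated(snp_ids)) stop_config("snp_specs", "duplicate SNP ids")
  for (s in config$snp_specs) {
    if (is.null(s$maf) || s$maf < 0 || s$maf > 0.5) {
      stop_config(paste0("snp_specs:", s$snp_id),
                  "maf must lie in [0, 0.5]")
    }
  }
  for (bid in names(config$ld_blocks)) {
    b <- config$ld_blocks[[bid]]
    if (abs(sum(b$hap_freqs) - 1) > 1e-9) {
      stop_config(paste0("ld_blocks:", bid),
                  "haplotype frequencies must sum to 1")
    }
    implied <- block_implied_mafs(b$hap_freqs, length(b$snps))
    stated <- vapply(b$snps, function(id) {
      config$snp_specs[[match(id, snp_ids)]]$maf
    }, numeric(1))
    if (any(abs(implied - stated) > 1e-6)) {
      stop_config(paste0("ld_blocks:", bid),
                  "haplotype frequencies inconsistent with stated per-SNP maf")
    }
    if (!all(b$snps %in% snp_ids)) {
      stop_config(paste0("ld_blocks:", bid), "block SNP missing from snp_specs")
    }
  }
  if (any(config$missingness_rates < 0 | config$missingness_rates >= 1)) {
    stop_config("missingness_rates", "probabilities must lie in [0, 1)")
  }
  cov_names <- names(config$covariate_specs)
  for (oname in names(config$outcome_models)) {
    m <- config$outcome_models[[oname]]
    if (!is.null(m$prevalence) && (m$prevalence <= 0 || m$prevalence >= 1)) {
      stop_config(paste0("outcome_models:", oname),
                  "prevalence must lie in (0, 1)")
    }
    for (tm in m$terms) {
      if (!is.null(tm$var) && !tm$var %in% cov_names) {
        stop_config(paste0("outcome_models:", oname),
                    sprintf("term refers to unknown covariate '%s'", tm$var))
      }
      if (!is.null(tm$snp) && !tm$snp %in% snp_ids) {
        stop_config(paste0("outcome_models:", oname),
                    sprintf("term refers to unknown SNP '%s'", tm$snp))
      }
      if (is.null(tm$var) && is.null(tm$snp)) {
        stop_config(paste0("outcome_models:", oname),
                    "term must name a covariate or a SNP")
      }
    }
  }
  invisible(config)
}

# ---------------------------------------------------------------------------
# Covariate sampling

# Solve for the log-normal sigma giving a target SD at a fixed median.
lognorm_sigma <- function(median, sd) {
  ratio <- sd / median
  f <- function(s) exp(s^2 / 2) * sqrt(exp(s^2) - 1) - ratio
  stats::uniroot(f, c(1e-6, 5))$root
}

sample_covariate <- function(spec, n) {
  switch(spec$type,
    truncnorm = {
      lo <- stats::pnorm(spec$range[1], spec$median, spec$sd)
      hi <- stats::pnorm(spec$range[2], spec$median, spec$sd)
      round(stats::qnorm(stats::runif(n, lo, hi), spec$median, spec$sd), 1)
    },
    lognorm = {
      mu <- log(spec$median)
      s <- lognorm_sigma(spec$median, spec$sd)
      lo <- stats::plnorm(spec$range[1], mu, s)
      hi <- stats::plnorm(spec$range[2], mu, s)
      round(stats::qlnorm(stats::runif(n, lo, hi), mu, s), 2)
    },
    karnofsky = {
      x <- round(stats::rnorm(n, spec$median, spec$sd) / 10) * 10
      pmin(pmax(x, spec$range[1]), spec$range[2])
    },
    binary = stats::runif(n) < spec$p,
    categorical = {
      p <- spec$counts / sum(spec$counts)
      factor(sample(spec$levels, n, replace = TRUE, prob = p),
             levels = spec$levels)
    },
    stop_config("covariate_specs", sprintf("unknown spec type '%s'", spec$type))
  )
}

# ---------------------------------------------------------------------------
# Genotype sampling

sample_genotypes <- function(config, n) {
  snp_ids <- vapply(config$snp_specs, `[[`, character(1), "snp_id")
  G <- matrix(NA_integer_, n, length(snp_ids),
              dimnames = list(NULL, snp_ids))
  in_block <- character(0)
  for (b in config$ld_blocks) {
    hap_alleles <- do.call(rbind, lapply(names(b$hap_freqs), function(h) {
      as.integer(strsplit(h, "")[[1]])
    }))
    idx1 <- sample.int(nrow(hap_alleles), n, replace = TRUE, prob = b$hap_freqs)
    idx2 <- sample.int(nrow(hap_alleles), n, replace = TRUE, prob = b$hap_freqs)
    G[, b$snps] <- hap_alleles[idx1, , drop = FALSE] +
      hap_alleles[idx2, , drop = FALSE]
    in_block <- c(in_block, b$snps)
  }
  for (s in config$snp_specs) {
    if (s$snp_id %in% in_block) next
    q <- s$maf
    G[, s$snp_id] <- stats::rbinom(n, 1, q) + stats::rbinom(n, 1, q)
  }
  G
}

# ---------------------------------------------------------------------------
# Outcome latents

# Linear predictor (without intercept) of an outcome model over a cohort.
# Covariate terms act on registry-transformed raw values; indicator terms
# (with a `level`) and logical covariates contribute 0/1.
model_linear_predictor <- function(model, covariates, genotypes) {
  n <- nrow(covariates)
  lp <- numeric(n)
  for (tm in model$terms) {
    if (!is.null(tm$var)) {
      x <- covariates[[tm$var]]
      if (!is.null(tm$level)) {
        v <- as.numeric(x == tm$level)
      } else if (is.logical(x)) {
        v <- as.numeric(x)
      } else {
        v <- apply_transform(registry_transform(tm$var), x)
      }
    } else {
      v <- encode_term(list(name = tm$snp, coding = tm$coding %||% "additive",
                            snps = tm$snp), genotypes)
      v <- as.numeric(v)
    }
    lp <- lp + tm$beta * v
  }
  lp
}

#' Calibrate a logistic model intercept to a target prevalence
#'
#' Finds, by monotone root-finding, the intercept for which the mean
#' fitted probability of the model over the given cohort equals the target
#' prevalence (to within 1e-6).
#'
#' @param model Outcome model spec (`terms`, each with `beta`).
#' @param target_prevalence Target mean risk, strictly inside (0, 1).
#' @param covariates Data frame of covariates.
#' @param genotypes Genotype matrix/data frame (needed when the model has
#'   genetic terms).
#' @return The calibrated intercept (a single number).
#' @export
calibrate_intercept <- function(model, target_prevalence, covariates,
                                genotypes = NULL) {
  if (!is.numeric(target_prevalence) || target_prevalence <= 0 ||
      target_prevalence >= 1) {
    stop("target_prevalence must lie strictly inside (0, 1)")
  }
  lp <- model_linear_predictor(model, covariates, genotypes)
  if (anyNA(lp)) lp <- lp[!is.na(lp)]
  f <- function(b0) mean(expit(b0 + lp)) - target_prevalence
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0) stop("target prevalence unattainable for this model")
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

# ---------------------------------------------------------------------------
# Instrument sampling conditional on latents

# All 16 high/low combinations of the four symptom indicators.
instrument_combos <- function() {
  m <- as.matrix(expand.grid(nausea = 0:1, tired = 0:1, depressed = 0:1,
                             constipation = 0:1))
  storage.mode(m) <- "integer"
  m
}

# Sample symptom indicators for each patient, conditional on the sickness,
# opioid-AE and cognitive latents, proportionally to the product of the
# marginal indicator probabilities over the combinations consistent with
# the latents. The latents are coupled upstream so a consistent
# combination always exists.
sample_instrument_indicators <- function(sick, opioid, cognitive, rates) {
  combos <- instrument_combos()
  w_all <- apply(combos, 1, function(x) {
    prod(ifelse(x == 1, rates, 1 - rates))
  })
  sick_of <- combos[, "nausea"] + combos[, "tired"] + combos[, "depressed"] >= 2
  op_part <- combos[, "nausea"] | combos[, "tired"] | combos[, "constipation"]
  n <- length(sick)
  out <- matrix(NA_integer_, n, 4, dimnames = list(NULL, colnames(combos)))
  key <- paste(sick, opioid, cognitive)
  for (k in unique(key)) {
    idx <- which(key == k)
    s <- sick[idx[1]]; o <- opioid[idx[1]]; cg <- cognitive[idx[1]]
    valid <- which(sick_of == s & (op_part | cg) == o)
    if (!length(valid)) stop("internal: inconsistent latent combination")
    pick <- if (length(valid) == 1) rep(valid, length(idx))
            else valid[sample.int(length(valid), length(idx), replace = TRUE,
                                  prob = w_all[valid])]
    out[idx, ] <- combos[pick, , drop = FALSE]
  }
  out
}

sample_int_range <- function(n, lo, hi) lo + floor(stats::runif(n) * (hi - lo + 1))

# ---------------------------------------------------------------------------

#' Generate a synthetic cohort
#'
#' Draws covariates from the configured marginals, genotypes per SNP under
#' Hardy-Weinberg equilibrium (or per LD block from haplotype
#' frequencies), binary outcome latents from the configured logistic
#' models with intercepts calibrated to the target prevalences, and
#' instrument scores conditional on the latents so that the phenotype
#' classifiers exactly recover them on complete records. Missingness is
#' applied per field, completely at random. Fixed seeds give byte-identical
#' cohorts.
#'
#' Outcome latents are made jointly consistent before instruments are
#' drawn: a sickness response (two of nausea/tiredness/depression) or
#' cognitive dysfunction (MMSE <= 23) necessarily also satisfies the
#' opioid adverse-event definition, so the adverse-event latent is the
#' union of its own model draw with those two.
#'
#' @param config A [cohort_config()].
#' @return Data frame of class `"pgx_cohort"`; one row per patient, with
#'   covariates, instrument scores and one genotype column per SNP.
#'   Attributes: `latents` (the generating outcome latents), `config`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  n <- config$n_patients
  with_seed(config$seed, {
    covariates <- as.data.frame(lapply(config$covariate_specs,
                                       sample_covariate, n = n))
    genotypes <- sample_genotypes(config, n)

    # instrument sampling needs all four latents: outcomes without a
    # configured model fall back to an intercept-only draw at the default
    # prevalence
    models <- config$outcome_models
    defaults <- default_outcome_models()
    for (oname in names(defaults)) {
      if (is.null(models[[oname]])) {
        models[[oname]] <- list(prevalence = defaults[[oname]]$prevalence,
                                terms = list())
      }
    }
    latents <- list()
    for (oname in setdiff(names(models), "opioid_ae_complaint")) {
      m <- models[[oname]]
      lp <- model_linear_predictor(m, covariates, genotypes)
      b0 <- calibrate_intercept(m, m$prevalence, covariates, genotypes)
      latents[[oname]] <- stats::runif(n) < expit(b0 + lp)
    }
    latents <- as.data.frame(latents)
    # A sickness response or cognitive dysfunction necessarily satisfies
    # the opioid adverse-event definition, so those latents force the AE
    # latent; the AE model draw applies to the remaining patients, with
    # its target prevalence adjusted so the overall prevalence still hits
    # the configured value (when attainable).
    if (!is.null(models$opioid_ae_complaint)) {
      m <- models$opioid_ae_complaint
      forced <- latents$sickness_response | latents$cognitive_dysfunction
      ae <- forced
      frac_forced <- mean(forced)
      target <- m$prevalence
      if (target > frac_forced && any(!forced)) {
        adj_target <- (target - frac_forced) / (1 - frac_forced)
        lp <- model_linear_predictor(m, covariates, genotypes)
        b0 <- calibrate_intercept(m, adj_target,
                                  covariates[!forced, , drop = FALSE],
                                  genotypes[!forced, , drop = FALSE])
        ae[!forced] <- stats::runif(sum(!forced)) < expit(b0 + lp[!forced])
      } else if (target <= frac_forced) {
        warning("opioid_ae_complaint target prevalence not attainable: ",
                "sickness/cognitive latents already force ",
                sprintf("%.3f", frac_forced))
      }
      latents$opioid_ae_complaint <- ae
    }

    bpi <- ifelse(latents$pain_control, sample_int_range(n, 0, 3),
                  sample_int_range(n, 4, 10))
    mmse <- ifelse(latents$cognitive_dysfunction, sample_int_range(n, 0, 23),
                   sample_int_range(n, 24, 30))
    ind <- sample_instrument_indicators(latents$sickness_response,
                                        latents$opioid_ae_complaint,
                                        latents$cognitive_dysfunction,
                                        config$instrument_rates)
    nausea <- ifelse(ind[, "nausea"] == 1, sample_int_range(n, 50, 100),
                     sample_int_range(n, 0, 49))
    constip <- ifelse(ind[, "constipation"] == 1, sample_int_range(n, 50, 100),
                      sample_int_range(n, 0, 49))
    tired <- ifelse(ind[, "tired"] == 1, sample_int_range(n, 3, 4),
                    sample_int_range(n, 1, 2))
    depressed <- ifelse(ind[, "depressed"] == 1, sample_int_range(n, 3, 4),
                        sample_int_range(n, 1, 2))

    cohort <- cbind(
      data.frame(id = sprintf("P%04d", seq_len(n))),
      covariates,
      data.frame(bpi_average_pain = bpi, mmse = mmse,
                 eortc_nausea_vomiting = nausea,
                 eortc_constipation = constip,
                 eortc_tired_item = tired,
                 eortc_depressed_item = depressed),
      as.data.frame(genotypes)
    )

    # missingness, completely at random per field
    rates <- config$missingness_rates
    snp_ids <- colnames(genotypes)
    for (field in names(rates)) {
      if (field == "genotype") {
        for (s in snp_ids) {
          cohort[[s]][stats::runif(n) < rates[[field]]] <- NA
        }
      } else if (field %in% names(cohort)) {
        cohort[[field]][stats::runif(n) < rates[[field]]] <- NA
      }
    }

    structure(cohort, latents = latents, config = config,
              class = c("pgx_cohort", "data.frame"))
  })
}

#' Genotype columns of a cohort
#'
#' @param cohort A cohort data frame produced by [generate_cohort()] or
#'   [read_cohort()].
#' @return Data frame of the 0/1/2 genotype columns, named by rs-ID.
#' @export
cohort_genotypes <- function(cohort) {
  config <- attr(cohort, "config")
  ids <- if (!is.null(config)) {
    vapply(config$snp_specs, `[[`, character(1), "snp_id")
  } else {
    grep("^rs[0-9]+$", names(cohort), value = TRUE)
  }
  as.data.frame(cohort)[, intersect(ids, names(cohort)), drop = FALSE]
}

# ---------------------------------------------------------------------------
# I/O

#' Write a cohort to CSV (with optional YAML config sidecar)
#'
#' One row per patient; genotype columns named by rs-ID; missing values as
#' empty cells.
#'
#' @param cohort Cohort data frame.
#' @param path Output CSV path.
#' @param config_path Optional path for a YAML sidecar describing the
#'   generating configuration (written only when the cohort carries one).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, config_path = NULL) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  config <- attr(cohort, "config")
  if (!is.null(config_path) && !is.null(config)) {
    yaml::write_yaml(config_as_list(config), config_path)
  }
  invisible(path)
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$missingness_rates <- as.list(out$missingness_rates)
  out$instrument_rates <- as.list(out$instrument_rates)
  out$ld_blocks <- lapply(out$ld_blocks, function(b) {
    list(snps = b$snps, hap_freqs = as.list(b$hap_freqs))
  })
  out
}

#' Read a cohort CSV written by [write_cohort()]
#'
#' @param path CSV path.
#' @return Cohort data frame (empty cells as NA).
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  for (v in c("sex", "centre_country", "ancestry_subgroup")) {
    if (v %in% names(df)) df[[v]] <- factor(df[[v]])
  }
  class(df) <- c("pgx_cohort", "data.frame")
  df
}

#' Export cohort genotypes as a minimal VCF
#'
#' Writes a VCFv4.2 file with one record per SNP and a GT-only FORMAT
#' field (unphased; missing genotypes as `./.`). Positions are synthetic
#' placeholders (sequential on chromosome "1") since the panel is defined
#' by rs-ID, not coordinates.
#'
#' @param cohort Cohort data frame.
#' @param path Output VCF path.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path) {
  g <- cohort_genotypes(cohort)
  ids <- if ("id" %in% names(cohort)) cohort$id else sprintf("S%d", seq_len(nrow(g)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_along(g)) {
    gt <- ifelse(is.na(g[[j]]), "./.", gt_code[g[[j]] + 1])
    writeLines(paste(c("1", j, names(g)[j], "A", "G", ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}
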