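# Shared fixtures: reduced SNP panels and cohort builders used across the
# suite. Simulation sizes here are chosen to keep each property check
# informative while the whole suite stays fast.

# 12-SNP analysis panel: the MYD88 carrier SNP plus a spread of
# independent SNPs and two LD blocks (one near-complete, one high-LD).
small_panel <- function() {
  p <- default_snp_panel()
  p$ld_blocks <- p$ld_blocks[c("CASP1", "ABCB1")]
  ind <- c("rs6853", "rs2794521", "rs6265", "rs1800629", "rs4680",
           "rs1799971", "rs10499563")
  keep <- c(ind, unlist(lapply(p$ld_blocks, `[[`, "snps")))
  p$snp_specs <- Filter(function(s) s$snp_id %in% keep, p$snp_specs)
  p
}

# Study-scale cohort on the reduced panel.
small_cohort <- function(seed, n = 468, outcome_models = default_outcome_models()) {
  add_phenotypes(generate_cohort(cohort_config(
    n_patients = n, seed = seed, snp_panel = small_panel(),
    outcome_models = outcome_models)))
}

# Outcome models with the genetic term removed from cognitive dysfunction
# (a cohort with purely non-genetic outcome structure).
null_genetic_models <- function() {
  m <- default_outcome_models()
  m$cognitive_dysfunction$terms <-
    Filter(function(tm) is.null(tm$snp), m$cognitive_dysfunction$terms)
  m
}

# Selection inputs for cognitive dysfunction with the age + Karnofsky
# base model fixed (the non-genetic predictors of that outcome).
cognitive_selection_data <- function(cohort) {
  stepdown_data(cohort, "cognitive_dysfunction",
                base_terms = c("age", "karnofsky"))
}

# HWE genotype vector at allele frequency q.
hwe_genotypes <- function(n, q) {
  stats::rbinom(n, 1, q) + stats::rbinom(n, 1, q)
}
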