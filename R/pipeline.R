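# Orchestration: run the full per-outcome analysis (phenotype
# classification -> genotype QC -> ancestry check -> lasso screen ->
# step-down genetic selection -> effect estimation -> GMDR -> permutation
# control) plus the adverse-event co-incidence table, with one root seed
# feeding named substreams per stage.

#' Build a pipeline run configuration
#'
#' @param input Path to a cohort CSV ([read_cohort()]), or `NULL` to
#'   simulate a cohort from `generator` at run time.
#' @param generator A [cohort_config()] used when `input` is `NULL`.
#' @param outcomes Phenotypes to analyse.
#' @param seed Root seed; every stage derives its own substream from it.
#' @param snps Analysis SNP set (default: all genotype columns).
#' @param codings Candidate genetic codings per SNP.
#' @param k_grid,folds,repeats Selection settings.
#' @param n_perm Permutations for the selection null (0 disables the
#'   permutation-control stage).
#' @param gmdr_orders Interaction orders for the GMDR search (empty vector
#'   disables GMDR).
#' @param gmdr_n_perm Permutations for the GMDR null per order.
#' @param out_dir Output directory for JSON/TSV reports, or `NULL` to skip
#'   writing files.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(input = NULL, generator = cohort_config(),
                       outcomes = phenotype_names(), seed = 1,
                       snps = NULL,
                       codings = c("dominant", "recessive", "genotypic"),
                       k_grid = seq(0, 10, by = 0.1), folds = 10,
                       repeats = 5, n_perm = 200, gmdr_orders = 1:2,
                       gmdr_n_perm = 50, out_dir = NULL) {
  if (!is.null(input) && !file.exists(input)) {
    stop_config("input", sprintf("file '%s' does not exist", input))
  }
  structure(list(input = input, generator = generator, outcomes = outcomes,
                 seed = seed, snps = snps, codings = codings, k_grid = k_grid,
                 folds = folds, repeats = repeats, n_perm = n_perm,
                 gmdr_orders = gmdr_orders, gmdr_n_perm = gmdr_n_perm,
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline run configuration from YAML
#'
#' Scalar fields of the YAML map onto [run_config()] arguments; the
#' `generator` block, when present, overrides `n_patients` and `seed` of
#' the default cohort generator.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  gen_args <- list()
  if (!is.null(cfg$generator)) {
    if (!is.null(cfg$generator$n_patients)) gen_args$n_patients <- cfg$generator$n_patients
    if (!is.null(cfg$generator$seed)) gen_args$seed <- cfg$generator$seed
  }
  args <- cfg[intersect(names(cfg), names(formals(run_config)))]
  args$generator <- do.call(cohort_config, gen_args)
  if (!is.null(args$k_grid) && length(args$k_grid) == 3 &&
      !is.null(names(cfg$k_grid))) {
    args$k_grid <- seq(cfg$k_grid$from, cfg$k_grid$to, by = cfg$k_grid$by)
  }
  do.call(run_config, args)
}

#' Run the full analysis pipeline
#'
#' Executes, per outcome: phenotype classification, genotype QC, the
#' ancestry-subgroup association check, the lasso screen for major
#' non-genetic predictors, step-down genetic selection with effect
#' estimates, the GMDR epistasis search with its permutation null, and
#' the permutation control of the selection CVE; plus the adverse-event
#' co-incidence matrix. Identical seeds give identical reports.
#'
#' @param config A [run_config()].
#' @return List of class `"pgx_report"` with elements `cohort_summary`,
#'   `qc`, `coincidence`, and one result list per outcome.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  cohort <- if (!is.null(config$input)) {
    read_cohort(config$input)
  } else {
    gen <- config$generator
    gen$seed <- derive_seed(seed, "simulate")
    generate_cohort(gen)
  }
  cohort <- add_phenotypes(cohort)
  genotypes <- cohort_genotypes(cohort)
  snps <- config$snps %||% names(genotypes)

  qc <- genotype_qc(genotypes[, snps, drop = FALSE])

  ae_flags <- data.frame(
    nausea = cohort$eortc_nausea_vomiting >= 50,
    tiredness = cohort$eortc_tired_item >= 3,
    depression = cohort$eortc_depressed_item >= 3,
    constipation = cohort$eortc_constipation >= 50,
    cognitive_dysfunction = cohort$cognitive_dysfunction)
  coincidence <- coincidence_matrix(ae_flags)

  results <- list()
  for (outcome in config$outcomes) {
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e) {
        stop(sprintf("[%s/%s] %s", outcome, what, conditionMessage(e)),
             call. = FALSE)
      })
    }
    res <- list(outcome = outcome)
    res$n <- sum(!is.na(cohort[[outcome]]))
    binary <- is.logical(cohort[[outcome]]) ||
      all(cohort[[outcome]] %in% c(0, 1, NA))
    res$n_events <- if (binary) sum(cohort[[outcome]], na.rm = TRUE) else NA

    res$ancestry_check <- stage("ancestry",
      if (binary && "ancestry_subgroup" %in% names(cohort)) {
        chisq_independence(cohort$ancestry_subgroup, cohort[[outcome]])[
          c("chi2", "df", "p_value")]
      })

    design <- stage("design", build_design(cohort, outcome))
    fam <- if (all(design$y %in% 0:1)) "binomial" else "gaussian"
    res$screen <- stage("screen", lasso_screen(
      design, folds = config$folds, family = fam,
      seed = derive_seed(seed, paste0("screen.", outcome))))
    base_terms <- res$screen$selected
    # interactions are only candidates in the screen; the base model keeps
    # main effects of every selected term as well
    mains <- unique(sub(" x log10\\(fentanyl\\)$", "", base_terms))
    base_terms <- union(mains[mains %in% colnames(design$x)], base_terms)

    data <- stage("select", stepdown_data(cohort, outcome,
                                          base_terms = base_terms,
                                          snps = snps,
                                          codings = config$codings))
    res$selection <- stage("select", stepdown_select(
      data$y, data$base_x, data$candidates, k_grid = config$k_grid,
      folds = config$folds, repeats = config$repeats,
      seed = derive_seed(seed, paste0("select.", outcome)),
      family = data$family))
    res$effects <- stage("effects", if (length(res$selection$selected)) {
      estimate_effects(res$selection,
                       seed = derive_seed(seed, paste0("effects.", outcome)))
    })

    if (length(config$gmdr_orders) && data$family == "binomial") {
      scores <- stage("gmdr", score_residuals(data$y, data$base_x))
      res$gmdr <- stage("gmdr", gmdr_search(
        scores, cohort_genotypes(cohort)[data$rows, snps, drop = FALSE],
        orders = config$gmdr_orders, folds = config$folds,
        seed = derive_seed(seed, paste0("gmdr.", outcome))))
      if (config$gmdr_n_perm > 0) {
        res$gmdr_null <- stage("gmdr", lapply(config$gmdr_orders, function(ord) {
          gmdr_null(scores,
                    cohort_genotypes(cohort)[data$rows, snps, drop = FALSE],
                    order = ord, n_perm = config$gmdr_n_perm,
                    seed = derive_seed(seed, paste0("gmdrnull.", outcome, ord)))
        }))
      }
    }

    if (config$n_perm > 0) {
      res$permutation <- stage("permtest", null_cve(
        data, observed = res$selection, n_perm = config$n_perm,
        k_grid = config$k_grid, folds = config$folds,
        repeats = config$repeats,
        seed = derive_seed(seed, paste0("perm.", outcome))))
    }
    results[[outcome]] <- res
  }

  report <- structure(list(
    n_patients = nrow(cohort),
    qc = qc, coincidence = coincidence, outcomes = results,
    seed = seed
  ), class = "pgx_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.pgx_report <- function(x, ...) {
  cat(sprintf("Pharmacogenetic pipeline report (n = %d, seed %s)\n",
              x$n_patients, x$seed))
  cat(sprintf("  QC: %d SNPs, min HWE p = %.3g\n", nrow(x$qc), min(x$qc$hwe_p)))
  for (res in x$outcomes) {
    cat(sprintf("\n== %s (n = %d, events = %s) ==\n",
                res$outcome, res$n, res$n_events))
    if (!is.null(res$ancestry_check)) {
      cat(sprintf("  ancestry subgroup chi2 p = %.3g\n",
                  res$ancestry_check$p_value))
    }
    cat(sprintf("  base model: %s\n",
                if (length(res$screen$selected))
                  paste(res$screen$selected, collapse = ", ")
                else "(none)"))
    print(res$selection)
    if (!is.null(res$permutation)) print(res$permutation)
    if (!is.null(res$gmdr)) print(res$gmdr)
  }
  invisible(x)
}

# Serialise a report to out_dir: JSON summary + TSV tables.
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$qc, file.path(out_dir, "qc_report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report$coincidence,
                     file.path(out_dir, "coincidence.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  summary_list <- lapply(report$outcomes, function(res) {
    out <- list(
      n = res$n, n_events = res$n_events,
      ancestry_p = res$ancestry_check$p_value,
      base_terms = res$screen$selected,
      selected = res$selection$selected,
      k = res$selection$k,
      cve = res$selection$cve, cve_base = res$selection$cve_base,
      auc = res$selection$auc)
    if (!is.null(res$permutation)) {
      out$permutation <- list(
        verdict = res$permutation$verdict,
        p_value = res$permutation$p_value,
        null_median = res$permutation$median,
        null_q25 = res$permutation$q25, null_q75 = res$permutation$q75)
    }
    if (!is.null(res$effects) && nrow(res$effects)) {
      out$effects <- res$effects
    }
    if (!is.null(res$gmdr)) {
      out$gmdr <- lapply(res$gmdr, function(r) {
        list(loci = r$loci, testing_accuracy = r$testing_accuracy,
             cv_consistency = r$cv_consistency)
      })
    }
    out
  })
  jsonlite::write_json(summary_list, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
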