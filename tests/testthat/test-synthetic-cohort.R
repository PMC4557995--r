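test_that("cohort configuration is validated with field-level messages", {
  expect_error(cohort_config(n_patients = 0), "n_patients")
  panel <- small_panel()
  panel$snp_specs[[1]]$maf <- 0.7
  expect_error(cohort_config(snp_panel = panel), "maf")
  panel2 <- small_panel()
  panel2$ld_blocks$CASP1$hap_freqs <- c("00" = 0.5, "11" = 0.4)
  expect_error(cohort_config(snp_panel = panel2), "sum to 1")
  models <- default_outcome_models()
  models$cognitive_dysfunction$terms[[1]]$var <- "not_a_covariate"
  expect_error(cohort_config(outcome_models = models), "unknown covariate")
  expect_error(
    cohort_config(missingness_rates = c(mmse = 1.0)), "missingness")
})

test_that("degenerate allele frequency gives all-wild-type genotypes", {
  panel <- small_panel()
  for (i in seq_along(panel$snp_specs)) {
    if (panel$snp_specs[[i]]$snp_id == "rs6265") panel$snp_specs[[i]]$maf <- 0
  }
  co <- generate_cohort(cohort_config(200, seed = 5, snp_panel = panel))
  expect_true(all(co$rs6265 == 0, na.rm = TRUE))
})

test_that("rs6853 carrier fraction matches its configured frequency", {
  co <- generate_cohort(cohort_config(10000, seed = 8,
                                      snp_panel = small_panel()))
  carrier <- mean(co$rs6853 >= 1, na.rm = TRUE)
  expect_lt(abs(carrier - 0.255), 0.02)
})

test_that("an intercept-only outcome model hits its target prevalence", {
  models <- list(cognitive_dysfunction = list(prevalence = 0.185,
                                              terms = list()))
  cfg <- cohort_config(10000, seed = 13, snp_panel = small_panel(),
                       outcome_models = models)
  co <- generate_cohort(cfg)
  prev <- mean(attr(co, "latents")$cognitive_dysfunction)
  half_width <- stats::qnorm(0.995) * sqrt(0.185 * 0.815 / 10000)
  expect_lt(abs(prev - 0.185), half_width)
})

test_that("calibrate_intercept solves the mean-risk equation", {
  cov <- data.frame(age = stats::runif(200, 30, 80),
                    karnofsky = sample(seq(20, 100, 10), 200, TRUE))
  no_slope <- list(terms = list())
  expect_equal(calibrate_intercept(no_slope, 0.5, cov), 0, tolerance = 1e-6)
  expect_equal(calibrate_intercept(no_slope, 0.185, cov),
               log(0.185 / 0.815), tolerance = 1e-6)

  tab3 <- list(terms = list(list(var = "age", beta = log(1.00037)),
                            list(var = "karnofsky", beta = log(0.63))))
  b0 <- calibrate_intercept(tab3, 81 / 438, cov)
  lp <- b0 + log(1.00037) * apply_boxcox(cov$age, 2) +
    log(0.63) * sqrt(cov$karnofsky)
  expect_equal(mean(1 / (1 + exp(-lp))), 81 / 438, tolerance = 1e-6)
  expect_error(calibrate_intercept(no_slope, 1.2, cov), "prevalence")
})

test_that("generated genotypes respect Hardy-Weinberg at scale", {
  co <- generate_cohort(cohort_config(10000, seed = 19,
                                      snp_panel = small_panel()))
  g <- cohort_genotypes(co)
  blocks <- small_panel()$ld_blocks
  blocked <- unlist(lapply(blocks, `[[`, "snps"))
  for (s in setdiff(names(g), blocked)) {
    counts <- c(sum(g[[s]] == 0, na.rm = TRUE), sum(g[[s]] == 1, na.rm = TRUE),
                sum(g[[s]] == 2, na.rm = TRUE))
    expect_gt(hwe_chisq(counts)$p_value, 0.001)
  }
})

test_that("LD blocks generate the configured haplotype structure", {
  co <- generate_cohort(cohort_config(5000, seed = 23,
                                      snp_panel = small_panel()))
  # CASP1 block is near-complete LD by construction
  ld <- pairwise_ld(co$rs554344, co$rs580253)
  expect_gt(ld$r2, 0.8)
  em <- em_haplotypes(stats::na.omit(cbind(co$rs554344, co$rs580253)))
  expect_equal(em$frequencies[["11"]], 0.36, tolerance = 0.03)
})

test_that("covariate marginals match their configured medians", {
  co <- generate_cohort(cohort_config(10000, seed = 29,
                                      snp_panel = small_panel()))
  specs <- default_covariate_specs()
  for (v in c("age", "bmi", "albumin", "creatinine_clearance",
              "serum_fentanyl_nM", "karnofsky")) {
    target <- specs[[v]]$median
    expect_lt(abs(stats::median(co[[v]], na.rm = TRUE) - target) / target,
              0.05, label = v)
  }
  expect_lt(abs(mean(co$sex == "male") - 218 / 468), 0.02)
  expect_lt(abs(mean(co$breakthrough_opioid) - 159 / 468), 0.02)
})

test_that("equal seeds give identical cohorts; different seeds differ", {
  cfg <- cohort_config(300, seed = 77, snp_panel = small_panel())
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  cfg2 <- cohort_config(300, seed = 78, snp_panel = small_panel())
  expect_false(identical(as.data.frame(a),
                         as.data.frame(generate_cohort(cfg2))))
})

test_that("cohort CSV and YAML sidecar round-trip", {
  co <- small_cohort(seed = 31, n = 120)
  csv <- tempfile(fileext = ".csv"); yml <- tempfile(fileext = ".yaml")
  write_cohort(co, csv, config_path = yml)
  back <- read_cohort(csv)
  expect_equal(nrow(back), 120)
  expect_equal(back$rs6853, co$rs6853)
  expect_equal(back$age, co$age)
  expect_equal(levels(back$sex), c("female", "male"))
  cfg <- yaml::read_yaml(yml)
  expect_equal(cfg$n_patients, 120)
  unlink(c(csv, yml))
})

test_that("minimal VCF export is well-formed GT-only VCF", {
  co <- generate_cohort(cohort_config(50, seed = 37,
                                      snp_panel = small_panel()))
  vcf <- tempfile(fileext = ".vcf")
  write_cohort_vcf(co, vcf)
  lines <- readLines(vcf)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  header <- strsplit(grep("^#CHROM", lines, value = TRUE), "\t")[[1]]
  expect_equal(length(header), 9 + 50)
  body <- strsplit(grep("^[^#]", lines, value = TRUE), "\t")
  expect_equal(length(body), ncol(cohort_genotypes(co)))
  gts <- unlist(lapply(body, `[`, -(1:9)))
  expect_true(all(gts %in% c("0/0", "0/1", "1/1", "./.")))
  unlink(vcf)
})
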