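# Independent HWE oracle: expected counts from the estimated allele
# frequency, Pearson statistic summed over the three genotype classes.
hwe_oracle <- function(counts) {
  n <- sum(counts)
  q <- (counts[2] + 2 * counts[3]) / (2 * n)
  if (q == 0 || q == 1) return(c(chi2 = 0, p = 1))
  e <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  chi2 <- sum((counts - e)^2 / e)
  c(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

test_that("hwe_chisq matches hand-computed and enumerated values", {
  res <- hwe_chisq(c(25, 50, 25))
  expect_equal(res$chi2, 0)
  expect_equal(res$p_value, 1)

  res <- hwe_chisq(c(30, 40, 30))
  expect_equal(res$chi2, 4)                        # expecteds 25/50/25
  expect_equal(res$p_value, 0.0455, tolerance = 1e-3)
  expect_equal(res$maf, 0.5)

  mono <- hwe_chisq(c(100, 0, 0))
  expect_equal(mono$chi2, 0)
  expect_equal(mono$maf, 0)

  expect_error(hwe_chisq(c(0, 0, 0)), "at least one")
  expect_error(hwe_chisq(c(-1, 2, 3)), "non-negative")
})

test_that("hwe_chisq agrees with the oracle on all triples with total <= 30", {
  for (total in c(1, 7, 18, 30)) {
    for (aa in 0:total) for (ab in 0:(total - aa)) {
      counts <- c(aa, ab, total - aa - ab)
      res <- hwe_chisq(counts)
      orc <- hwe_oracle(counts)
      expect_equal(res$chi2, orc[["chi2"]], tolerance = 1e-12,
                   label = paste(counts, collapse = "/"))
      expect_equal(res$p_value, orc[["p"]], tolerance = 1e-12)
    }
  }
})

test_that("on HWE cohorts about 10% of SNPs fall below HWE p of 0.1", {
  withr::with_seed(62, {
    below <- replicate(40, {
      g <- hwe_genotypes(2000, stats::runif(1, 0.1, 0.5))
      hwe_chisq(tabulate(g + 1, 3))$p_value < 0.1
    })
  })
  se <- sqrt(0.1 * 0.9 / 40)
  expect_lt(abs(mean(below) - 0.1), 3 * se + 1e-9)
})

test_that("pairwise_ld spans the no-LD to complete-LD range", {
  withr::with_seed(17, {
    g1 <- hwe_genotypes(5000, 0.3)
    g2 <- hwe_genotypes(5000, 0.4)
  })
  expect_equal(pairwise_ld(g1, g1)$r2, 1, tolerance = 1e-6)
  expect_equal(pairwise_ld(g1, g1)$d_prime, 1, tolerance = 1e-6)

  indep <- pairwise_ld(g1, g2)
  expect_lt(indep$r2, 0.01)

  # complete LD: haplotypes 00 and 11 only, frequency 0.5 each
  withr::with_seed(18, {
    h1 <- stats::rbinom(5000, 1, 0.5); h2 <- stats::rbinom(5000, 1, 0.5)
  })
  res <- pairwise_ld(h1 + h2, h1 + h2)
  expect_equal(res$r2, 1, tolerance = 1e-6)

  mono <- pairwise_ld(rep(0L, 100), g2[1:100])
  expect_false(mono$defined)
  expect_true(is.na(mono$r2))
})

test_that("em_haplotypes: trivial, closed-form and recovery cases", {
  # single SNP: haplotype frequencies are the allele frequencies
  withr::with_seed(3, g <- matrix(hwe_genotypes(500, 0.3), ncol = 1))
  em <- em_haplotypes(g)
  expect_equal(sum(em$frequencies), 1, tolerance = 1e-9)
  expect_equal(em$frequencies[["1"]], mean(g) / 2, tolerance = 1e-6)

  # two SNPs, no double heterozygotes: phase is unambiguous, so the EM
  # estimate equals direct haplotype counting
  g2 <- rbind(c(0, 0), c(0, 0), c(2, 2), c(1, 0), c(0, 1), c(2, 0),
              c(1, 1) * 0, c(2, 1))
  em2 <- em_haplotypes(g2)
  hap_count <- c("00" = 0, "10" = 0, "01" = 0, "11" = 0)
  for (i in seq_len(nrow(g2))) {
    gi <- g2[i, ]
    het <- which(gi == 1)
    h_base <- ifelse(gi == 2, 1, 0)
    if (length(het) == 0) {
      lab <- paste(h_base, collapse = "")
      hap_count[lab] <- hap_count[lab] + 2
    } else {
      h1 <- h_base; h1[het] <- 1
      h2 <- h_base; h2[het] <- 0
      hap_count[paste(h1, collapse = "")] <- hap_count[paste(h1, collapse = "")] + 1
      hap_count[paste(h2, collapse = "")] <- hap_count[paste(h2, collapse = "")] + 1
    }
  }
  expect_equal(em2$frequencies[names(hap_count)],
               hap_count / sum(hap_count), tolerance = 1e-6)

  # parameter recovery from a known 3-SNP haplotype distribution
  freqs <- c("000" = 0.4, "111" = 0.3, "100" = 0.2, "011" = 0.1)
  alle <- do.call(rbind, lapply(names(freqs),
                                function(h) as.integer(strsplit(h, "")[[1]])))
  withr::with_seed(44, {
    i1 <- sample(4, 2000, TRUE, prob = freqs)
    i2 <- sample(4, 2000, TRUE, prob = freqs)
  })
  g3 <- alle[i1, ] + alle[i2, ]
  em3 <- em_haplotypes(g3)
  expect_true(em3$converged)
  expect_lt(max(abs(em3$frequencies[names(freqs)] - freqs)), 0.02)
  # log-likelihood is monotone non-decreasing
  expect_true(all(diff(em3$loglik) > -1e-8))
})

test_that("encode_term produces the study's genetic codings", {
  g <- data.frame(rs1 = c(0, 1, 2, NA), rs2 = c(2, 2, 0, 1))
  dom <- encode_term(list(name = "rs1", coding = "dominant", snps = "rs1"), g)
  expect_equal(dom, c(0, 1, 1, NA))
  rec <- encode_term(list(name = "rs1", coding = "recessive", snps = "rs1"), g)
  expect_equal(rec, c(0, 0, 1, NA))
  add <- encode_term(list(name = "rs1", coding = "additive", snps = "rs1"), g)
  expect_equal(add, c(0, 1, 2, NA))
  gen <- encode_term(list(name = "rs1", coding = "genotypic", snps = "rs1"), g)
  expect_equal(as.character(gen), c("wt", "het", "hom", NA))
  expect_error(encode_term(list(name = "x", coding = "dominant",
                                snps = "rs9"), g), "not present")
})

test_that("genotype_qc summarises call rate, MAF and HWE per SNP", {
  withr::with_seed(91, {
    g <- data.frame(rs1 = hwe_genotypes(300, 0.2), rs2 = hwe_genotypes(300, 0.45))
    g$rs1[1:15] <- NA
  })
  qc <- genotype_qc(g)
  expect_equal(qc$snp_id, c("rs1", "rs2"))
  expect_equal(qc$call_rate[1], 285 / 300)
  expect_equal(qc$n_AA + qc$n_Aa + qc$n_aa, qc$n)
  expect_true(all(qc$hwe_p > 0.001))
})
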