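# Genotype quality control and genetic codings: allele frequencies,
# Hardy-Weinberg chi-squared tests, pairwise linkage disequilibrium from
# EM-estimated haplotype frequencies, EM haplotype inference for small
# within-gene blocks, and numeric/categorical codings of genetic terms.

#' Hardy-Weinberg equilibrium chi-squared test
#'
#' Estimates the variant allele frequency from the genotype counts,
#' computes the expected genotype counts under Hardy-Weinberg proportions
#' ((1-q)^2, 2q(1-q), q^2), and returns the 1-df Pearson chi-squared
#' statistic with its upper-tail p-value. A monomorphic SNP fits its
#' expectation exactly (chi2 = 0, p = 1).
#'
#' @param counts Integer vector `(n_AA, n_Aa, n_aa)` of homozygous
#'   wild-type, heterozygous and homozygous variant counts.
#' @param snp_id Optional SNP identifier carried into the result.
#' @return List of class `"hwe_result"` with `snp_id`, `chi2`, `p_value`,
#'   `maf`, `n` and `expected` counts.
#' @examples
#' hwe_chisq(c(30, 40, 30))  # chi2 = 4, p ~ 0.0455
#' @export
hwe_chisq <- function(counts, snp_id = NA_character_) {
  if (length(counts) != 3 || any(is.na(counts)) || any(counts < 0)) {
    stop("counts must be three non-negative genotype counts (n_AA, n_Aa, n_aa)")
  }
  n <- sum(counts)
  if (n < 1) stop("at least one genotyped subject required")
  q <- (2 * counts[3] + counts[2]) / (2 * n)
  expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  if (q == 0 || q == 1) {
    chi2 <- 0
  } else {
    chi2 <- sum((counts - expected)^2 / expected)
  }
  structure(list(snp_id = snp_id, chi2 = chi2,
                 p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                 maf = q, n = n, expected = expected),
            class = "hwe_result")
}

# Enumerate haplotype pairs compatible with one multilocus genotype.
# Haplotypes are integer codes whose bits (1-based from SNP 1 = lowest bit)
# give the allele carried at each SNP.
compatible_pairs <- function(g) {
  L <- length(g)
  het <- which(g == 1)
  base <- sum((g == 2) * 2^(seq_len(L) - 1))
  if (length(het) == 0) return(matrix(c(base, base), ncol = 2))
  masks <- 2^(het - 1)
  k <- length(het)
  # assign each heterozygous SNP's variant allele to hap1 or hap2
  assign <- as.matrix(expand.grid(rep(list(0:1), k)))
  h1 <- base + assign %*% masks
  h2 <- base + (1 - assign) %*% masks
  pairs <- cbind(as.vector(h1), as.vector(h2))
  # unordered pairs: keep h1 <= h2, unique
  pairs <- unique(t(apply(pairs, 1, sort)))
  matrix(pairs, ncol = 2)
}

# Allele string for a haplotype code, SNP 1 leftmost.
hap_label <- function(code, L) {
  paste(as.integer(intToBits(code))[seq_len(L)], collapse = "")
}

#' EM haplotype-frequency estimation for a small SNP block
#'
#' Standard expectation-maximisation over phase-ambiguous multilocus
#' genotypes for a block of up to 8 biallelic SNPs: the E-step distributes
#' each subject's mass over the haplotype pairs compatible with their
#' genotype in proportion to current pair probabilities, and the M-step
#' re-estimates haplotype frequencies from the expected counts. The
#' observed-data log-likelihood is non-decreasing over iterations.
#'
#' @param block Matrix or data frame of genotypes (subjects x SNPs, values
#'   0/1/2; rows with any NA are dropped).
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the log-likelihood change.
#' @return List of class `"em_haplotypes"`: `frequencies` (named by
#'   haplotype allele string, SNP order as given), `loglik` (trace),
#'   `converged`, `n_iter`, `n_used`, and `diplotypes` — per retained
#'   subject the maximum-posterior phase as `"h1|h2"` (ties broken
#'   lexicographically).
#' @export
em_haplotypes <- function(block, max_iter = 200, tol = 1e-8) {
  block <- as.matrix(block)
  L <- ncol(block)
  if (L > 8) stop("blocks are limited to 8 SNPs")
  keep <- stats::complete.cases(block)
  g <- block[keep, , drop = FALSE]
  if (nrow(g) == 0) stop("no complete multilocus genotypes")
  if (!all(g %in% 0:2)) stop("genotypes must be 0, 1 or 2 copies of the variant allele")

  H <- 2^L
  pair_list <- apply(g, 1, compatible_pairs, simplify = FALSE)
  freq <- rep(1 / H, H)
  loglik <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    exp_counts <- numeric(H)
    ll <- 0
    post_list <- vector("list", length(pair_list))
    for (i in seq_along(pair_list)) {
      p <- pair_list[[i]]
      w <- freq[p[, 1] + 1] * freq[p[, 2] + 1] * ifelse(p[, 1] == p[, 2], 1, 2)
      tw <- sum(w)
      if (tw <= 0) { w <- rep(1 / length(w), length(w)); tw <- 1 }
      ll <- ll + log(tw)
      post <- w / tw
      post_list[[i]] <- post
      for (j in seq_len(nrow(p))) {
        exp_counts[p[j, 1] + 1] <- exp_counts[p[j, 1] + 1] + post[j]
        exp_counts[p[j, 2] + 1] <- exp_counts[p[j, 2] + 1] + post[j]
      }
    }
    loglik <- c(loglik, ll)
    freq_new <- exp_counts / sum(exp_counts)
    if (it > 1 && abs(loglik[it] - loglik[it - 1]) < tol) {
      converged <- TRUE
      freq <- freq_new
      break
    }
    freq <- freq_new
  }

  labels <- vapply(0:(H - 1), hap_label, character(1), L = L)
  names(freq) <- labels
  diplo <- vapply(seq_along(pair_list), function(i) {
    p <- pair_list[[i]]
    post <- post_list[[i]]
    lab <- vapply(seq_len(nrow(p)), function(j) {
      paste(sort(c(labels[p[j, 1] + 1], labels[p[j, 2] + 1])), collapse = "|")
    }, character(1))
    best <- which(post == max(post))
    lab[best][order(lab[best])][1]
  }, character(1))

  structure(list(frequencies = freq, loglik = loglik, converged = converged,
                 n_iter = length(loglik), n_used = nrow(g),
                 used_rows = which(keep), diplotypes = diplo),
            class = "em_haplotypes")
}

#' Pairwise linkage disequilibrium between two SNPs
#'
#' Haplotype frequencies for the SNP pair are estimated by EM from
#' unphased genotypes; r-squared is the squared allelic correlation
#' D^2 / (pA qA pB qB) and D' is D normalised by its bound at the
#' observed allele frequencies.
#'
#' @param g1,g2 Genotype vectors (0/1/2, NA allowed) for the two SNPs.
#' @return List of class `"ld_result"` with `r2`, `d_prime`, `d`,
#'   `maf` (both SNPs), `n` and `defined` (FALSE for a monomorphic SNP,
#'   where LD is undefined).
#' @export
pairwise_ld <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2) stop("need at least 2 complete genotype pairs")
  g <- cbind(g1[ok], g2[ok])
  p1 <- mean(g[, 1]) / 2
  p2 <- mean(g[, 2]) / 2
  if (p1 %in% c(0, 1) || p2 %in% c(0, 1)) {
    return(structure(list(r2 = NA_real_, d_prime = NA_real_, d = NA_real_,
                          maf = c(p1, p2), n = sum(ok), defined = FALSE),
                     class = "ld_result"))
  }
  em <- em_haplotypes(g)
  f <- em$frequencies  # labels "00","10","01","11", SNP1 allele leftmost
  f11 <- f[["11"]]
  pA <- f[["10"]] + f11  # variant allele at SNP1
  pB <- f[["01"]] + f11  # variant allele at SNP2
  d <- f11 - pA * pB
  dmax <- if (d >= 0) min(pA * (1 - pB), (1 - pA) * pB) else min(pA * pB, (1 - pA) * (1 - pB))
  structure(list(r2 = d^2 / (pA * (1 - pA) * pB * (1 - pB)),
                 d_prime = if (dmax > 0) abs(d) / dmax else NA_real_,
                 d = d, maf = c(pA, pB), n = sum(ok), defined = TRUE),
            class = "ld_result")
}

#' Code a genetic term from a genotype matrix
#'
#' Supported codings of 0/1/2 variant-allele dosages: `additive` (copies),
#' `dominant` (variant carrier: 1 when at least one copy), `recessive`
#' (homozygous variant), `genotypic` (three-level factor with homozygous
#' wild-type as reference), and `diplotype` (most-likely multilocus phase
#' labels from [em_haplotypes()] over the term's SNPs). Missing genotypes
#' give missing coded values.
#'
#' @param term List with `name`, `coding` and `snps` (character vector of
#'   SNP column names; a single SNP except for `diplotype`).
#' @param genotypes Data frame or matrix with one column per SNP.
#' @return Numeric vector (additive/dominant/recessive), or factor
#'   (genotypic/diplotype), one value per row of `genotypes`.
#' @export
encode_term <- function(term, genotypes) {
  genotypes <- as.data.frame(genotypes)
  if (!all(term$snps %in% names(genotypes))) {
    stop("term SNPs not present in genotype matrix: ",
         paste(setdiff(term$snps, names(genotypes)), collapse = ", "))
  }
  if (term$coding != "diplotype" && length(term$snps) != 1) {
    stop("single-SNP coding requires exactly one SNP")
  }
  g <- genotypes[[term$snps[1]]]
  switch(term$coding,
    additive  = as.numeric(g),
    dominant  = as.numeric(g >= 1),
    recessive = as.numeric(g == 2),
    genotypic = factor(g, levels = 0:2, labels = c("wt", "het", "hom")),
    diplotype = {
      em <- em_haplotypes(genotypes[, term$snps, drop = FALSE])
      out <- rep(NA_character_, nrow(genotypes))
      out[em$used_rows] <- em$diplotypes
      factor(out)
    },
    stop(sprintf("unknown coding '%s'", term$coding))
  )
}

#' Per-SNP genotype QC report
#'
#' Summarises each genotype column: call rate, genotype counts, variant
#' allele frequency and the Hardy-Weinberg chi-squared test.
#'
#' @param genotypes Data frame/matrix of 0/1/2 genotype columns.
#' @return Data frame with one row per SNP: `snp_id`, `n`, `call_rate`,
#'   `n_AA`, `n_Aa`, `n_aa`, `maf`, `hwe_chi2`, `hwe_p`.
#' @export
genotype_qc <- function(genotypes) {
  genotypes <- as.data.frame(genotypes)
  rows <- lapply(names(genotypes), function(s) {
    g <- genotypes[[s]]
    counts <- c(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
                sum(g == 2, na.rm = TRUE))
    h <- hwe_chisq(counts, snp_id = s)
    data.frame(snp_id = s, n = sum(!is.na(g)),
               call_rate = mean(!is.na(g)),
               n_AA = counts[1], n_Aa = counts[2], n_aa = counts[3],
               maf = h$maf, hwe_chi2 = h$chi2, hwe_p = h$p_value)
  })
  do.call(rbind, rows)
}
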