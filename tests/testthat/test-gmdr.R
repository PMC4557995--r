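# Brute-force GMDR oracle for small panels at order 2: enumerates every
# SNP pair and recomputes cell labels and weighted testing accuracy
# directly from the definition.
gmdr_oracle_order2 <- function(s, G, foldid) {
  snps <- colnames(G)
  pairs <- utils::combn(snps, 2, simplify = FALSE)
  folds <- max(foldid)
  acc <- sapply(pairs, function(pr) {
    cell <- paste(G[, pr[1]], G[, pr[2]])
    cell[is.na(G[, pr[1]]) | is.na(G[, pr[2]])] <- NA
    mean(sapply(seq_len(folds), function(f) {
      test <- foldid == f
      lab <- tapply(s[!test & !is.na(cell)], cell[!test & !is.na(cell)], sum) > 0
      te <- which(test & !is.na(cell))
      tl <- lab[cell[te]]
      known <- !is.na(tl)
      if (!any(known)) return(NA_real_)
      si <- s[te][known]
      sum(abs(si)[tl[known] == (si >= 0)]) / sum(abs(si))
    }), na.rm = TRUE)
  })
  list(best = pairs[[which.max(acc)]], acc = max(acc), all = acc)
}

test_that("score residuals are centred fit residuals", {
  y <- rep(c(0, 1), 100)
  s <- score_residuals(y)
  expect_equal(sort(unique(round(s, 10))), c(-0.5, 0.5))
  expect_lt(abs(mean(s)), 1e-8)

  withr::with_seed(7, {
    x <- matrix(stats::rnorm(400), dimnames = list(NULL, "z"))
    yy <- as.numeric(stats::runif(400) < 1 / (1 + exp(-x[, 1])))
  })
  s2 <- score_residuals(yy, x)
  expect_lt(abs(mean(s2)), 1e-8)

  # perfectly predictive covariate drives all scores to (numerically) zero
  s3 <- suppressWarnings(score_residuals(yy, matrix(yy, dimnames = list(NULL, "y"))))
  expect_lt(max(abs(s3)), 1e-4)
})

test_that("all-positive scores give universal high-risk cells and accuracy 1", {
  withr::with_seed(11, {
    G <- data.frame(rs1 = hwe_genotypes(200, 0.3), rs2 = hwe_genotypes(200, 0.4))
    s <- stats::runif(200, 0.1, 1)
  })
  res <- gmdr_search(s, G, orders = 1:2, folds = 5, seed = 1)
  for (r in res) {
    expect_equal(r$testing_accuracy, 1)
    expect_true(all(r$cell_labels == "high"))
  }
})

test_that("testing accuracy is invariant to positive rescaling of scores", {
  withr::with_seed(13, {
    G <- data.frame(rs1 = hwe_genotypes(300, 0.3), rs2 = hwe_genotypes(300, 0.4),
                    rs3 = hwe_genotypes(300, 0.2))
    s <- stats::rnorm(300)
  })
  a <- gmdr_search(s, G, orders = 2, folds = 5, seed = 9)
  b <- gmdr_search(s * 7.3, G, orders = 2, folds = 5, seed = 9)
  expect_equal(a[["2"]]$testing_accuracy, b[["2"]]$testing_accuracy)
  expect_identical(a[["2"]]$loci, b[["2"]]$loci)
})

test_that("gmdr_search matches the exhaustive order-2 oracle", {
  withr::with_seed(17, {
    G <- data.frame(rs1 = hwe_genotypes(250, 0.3), rs2 = hwe_genotypes(250, 0.4),
                    rs3 = hwe_genotypes(250, 0.2), rs4 = hwe_genotypes(250, 0.45))
    s <- stats::rnorm(250)
  })
  res <- gmdr_search(s, G, orders = 2, folds = 5, seed = 21)[["2"]]
  foldid <- pgxpipe:::make_folds(as.numeric(s >= 0), 5,
                                 seed = pgxpipe:::derive_seed(21, "gmdr"))
  orc <- gmdr_oracle_order2(s, as.matrix(G), foldid)
  expect_identical(sort(res$loci), sort(orc$best))
  expect_equal(res$testing_accuracy, orc$acc, tolerance = 1e-12)
  expect_equal(sort(res$combinations$testing_accuracy), sort(orc$all),
               tolerance = 1e-12)
})

test_that("null scores give testing accuracy near one half", {
  withr::with_seed(23, {
    G <- as.data.frame(replicate(5, hwe_genotypes(1000, 0.35)))
    names(G) <- paste0("rs", 1:5)
    s <- stats::rnorm(1000)
  })
  res <- gmdr_search(s, G, orders = 2, folds = 10, seed = 27)
  expect_lt(abs(res[["2"]]$testing_accuracy - 0.5), 0.06)
})

test_that("a planted two-locus interaction is identified with high consistency", {
  withr::with_seed(29, {
    n <- 1000
    G <- as.data.frame(replicate(6, hwe_genotypes(n, 0.4)))
    names(G) <- paste0("rs", 1:6)
    # XOR-type penetrance on carriers of rs2 and rs5
    risk <- xor(G$rs2 >= 1, G$rs5 >= 1)
    y <- as.numeric(stats::runif(n) < ifelse(risk, 0.65, 0.15))
  })
  s <- score_residuals(y)
  res <- gmdr_search(s, G, orders = 2, folds = 10, seed = 31)[["2"]]
  expect_setequal(res$loci, c("rs2", "rs5"))
  expect_gte(res$cv_consistency, 8)
  expect_gt(res$testing_accuracy, 0.6)
})

test_that("a single-locus dominant effect tops the order-1 ranking", {
  withr::with_seed(37, {
    n <- 800
    G <- as.data.frame(replicate(5, hwe_genotypes(n, 0.35)))
    names(G) <- paste0("rs", 1:5)
    y <- as.numeric(stats::runif(n) < ifelse(G$rs3 >= 1, 0.5, 0.2))
  })
  res <- gmdr_search(score_residuals(y), G, orders = 1, folds = 10,
                     seed = 41)[["1"]]
  expect_identical(res$loci, "rs3")
})

test_that("gmdr_null calibrates the observed accuracy", {
  withr::with_seed(43, {
    n <- 600
    G <- as.data.frame(replicate(4, hwe_genotypes(n, 0.4)))
    names(G) <- paste0("rs", 1:4)
    risk <- xor(G$rs1 >= 1, G$rs4 >= 1)
    y <- as.numeric(stats::runif(n) < ifelse(risk, 0.7, 0.12))
  })
  s <- score_residuals(y)
  res <- gmdr_null(s, G, order = 2, n_perm = 30, seed = 47)
  expect_equal(res$p_value, 1 / 31, tolerance = 1e-9)
  expect_gt(res$observed, max(res$null_accuracy))
  expect_error(gmdr_null(s, G, order = 2, n_perm = 0), "at least 1")
})

test_that("missing genotypes and guards are handled", {
  withr::with_seed(53, {
    G <- data.frame(rs1 = hwe_genotypes(300, 0.3), rs2 = hwe_genotypes(300, 0.4))
    G$rs1[1:20] <- NA
    s <- stats::rnorm(300)
  })
  res <- gmdr_search(s, G, orders = 1:2, folds = 5, seed = 3)
  expect_true(is.finite(res[["2"]]$testing_accuracy))
  expect_error(gmdr_search(s, G, orders = 3, folds = 5, seed = 3),
               "order exceeds")
})
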