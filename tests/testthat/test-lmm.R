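test_that("compute_grm conventions behave as expected", {
  w <- ail_world()
  ids <- w$ped$individual_id[w$ped$generation == 6]
  g <- subset_genotypes(w$geno, samples = ids)
  G <- compute_grm(g)
  expect_true(isSymmetric(G))
  # duplicate individuals: off-diagonal equals the diagonal value
  g2 <- g
  g2$dosage <- cbind(g$dosage, dup = g$dosage[, 1])
  g2 <- genotype_matrix(g2$dosage, g$map, c(g$samples, "dup"))
  G2 <- compute_grm(g2)
  expect_equal(G2[ids[1], "dup"], G2["dup", "dup"])
  # excluding the only chromosomes errors
  expect_error(compute_grm(subset_genotypes(g, snps = g$map$chrom == "1"),
                           exclude_chrom = "1"), "SNPs")
  # standardized convention: mean diagonal ~ 1 on HWE-ish data
  Gs <- compute_grm(g, type = "standardized")
  expect_equal(mean(diag(Gs)), 1, tolerance = 0.05)
})

test_that("fit_null recovers variance components and matches the grid oracle", {
  w <- ail_world()
  ids <- w$ped$individual_id[w$ped$generation >= 5]
  A <- 2 * w$kin[ids, ids]
  # pure noise -> boundary fit near lambda = 0
  set.seed(1)
  y0 <- rnorm(length(ids))
  f0 <- fit_null(y0, NULL, A)
  expect_lt(f0$h2, 0.15)
  # h2 = 0.5 recovery at n ~ 500 on a family-structured relationship matrix
  ped5 <- build_ail_pedigree(63, 5, 4, seed = 17)
  ids5 <- ped5$individual_id[ped5$generation >= 4]
  A5 <- 2 * kinship_from_pedigree(ped5)[ids5, ids5]
  eA <- eigen(A5, symmetric = TRUE)
  L <- eA$vectors %*% (sqrt(pmax(eA$values, 0)) * t(eA$vectors))
  h2hat <- sapply(1:5, function(s) {
    set.seed(s)
    y <- sqrt(0.5) * drop(L %*% rnorm(length(ids5))) +
      sqrt(0.5) * rnorm(length(ids5))
    fit_null(y, NULL, A5)$h2
  })
  expect_true(all(abs(h2hat - 0.5) < 0.15))
  # REML log-likelihood matches a dense grid oracle at n = 12
  set.seed(3)
  n <- 12
  X <- matrix(rnorm(n * 6), n)
  K <- tcrossprod(scale(X)) / 6 + diag(n) * 0.01
  W <- cbind(1, rnorm(n))
  y <- rnorm(n) + drop(K %*% rnorm(n))
  fit <- fit_null(y, W, K)
  grid <- 10^seq(-5, 5, length.out = 2000)
  oracle <- reml_grid_oracle(y, W, K, grid)
  expect_equal(fit$loglik_reml, max(oracle), tolerance = 1e-6)
  expect_equal(log10(fit$lambda_ratio), log10(grid[which.max(oracle)]),
               tolerance = 0.02)
  # non-finite y errors with the offending samples
  yb <- y; yb[3] <- NA
  expect_error(fit_null(yb, W, K), "3")
})

test_that("assoc_scan equals OLS without kinship and the dense GLS oracle with", {
  set.seed(5)
  n <- 60
  g <- random_geno(1, n, seed = 5)
  x <- g$dosage[1, ]
  W <- cbind(rnorm(n))
  y <- 0.3 * x + rnorm(n)
  tab <- assoc_scan(y, W, g, loco = FALSE)
  ls <- summary(lm(y ~ W + x))$coefficients["x", ]
  expect_equal(tab$beta, unname(ls[1]), tolerance = 1e-12)
  expect_equal(tab$se, unname(ls[2]), tolerance = 1e-12)
  expect_equal(tab$p, unname(ls[4]), tolerance = 1e-12)
  # dense GLS oracle on n = 10 instances with a structured K
  for (s in 1:5) {
    set.seed(s)
    n <- 10
    Z <- matrix(rnorm(n * 4), n)
    K <- tcrossprod(Z) / 4 + diag(n)
    x <- rbinom(n, 2, 0.5)
    W <- cbind(1, rnorm(n))
    y <- 0.5 * x + drop(Z %*% rnorm(4)) + rnorm(n)
    gm <- toy_geno(matrix(x, 1))
    tab <- assoc_scan(y, W[, 2, drop = FALSE], gm, loco = FALSE, K = K)
    fit <- fit_null(y, W, K)
    o <- gls_oracle(y, W, x, K, fit)
    expect_equal(tab$beta, unname(o["beta"]), tolerance = 1e-8)
    expect_equal(tab$se, unname(o["se"]), tolerance = 1e-8)
    expect_equal(tab$p, unname(o["p"]), tolerance = 1e-8)
  }
})

test_that("scan handles monomorphic SNPs and controls type-I error", {
  set.seed(9)
  n <- 300
  D <- matrix(rbinom(1000 * n, 2, 0.5), 1000, n)
  D[7, ] <- 2   # monomorphic
  g <- toy_geno(D)
  y <- rnorm(n)
  tab <- assoc_scan(y[sample.int(n)], NULL, g, loco = FALSE)
  expect_true(tab$monomorphic[7])
  expect_equal(tab$p[7], 1)
  expect_equal(tab$beta[7], 0)
  # permuted trait: ~5% of independent SNPs below 0.05
  frac <- mean(tab$p[-7] < 0.05)
  expect_gt(frac, 0.05 - 3 * sqrt(0.05 * 0.95 / 999))
  expect_lt(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / 999))
})

test_that("LMM scan keeps type-I error and beta unbiasedness under structure", {
  w <- ail_world()
  ids <- w$ped$individual_id[w$ped$generation >= 5]
  g <- subset_genotypes(w$geno, samples = ids)
  A <- 2 * w$kin[ids, ids]
  snp <- 25  # mid-chromosome SNP
  betas <- sapply(1:60, function(s) {
    sp <- trait_sim_spec("quantitative", causal_snps = g$map$snp[snp],
                         beta = 0.25, sigma_g2 = 0.4, sigma_e2 = 0.6,
                         seed = 100 + s)
    y <- simulate_phenotypes(g, A, sp)$value
    fit <- fit_null(y, NULL, A)
    tr <- ailrep:::whiten(fit)
    ailrep:::scan_core(y, matrix(1, length(y), 1),
                       cbind(g$dosage[snp, ]), tr)$beta
  })
  # unbiased within Monte-Carlo error
  expect_lt(abs(mean(betas) - 0.25), 3 * sd(betas) / sqrt(length(betas)))
})

test_that("quantile_normalize is a rank-based inverse normal transform", {
  expect_equal(quantile_normalize(c(3, 10)),
               qnorm(c(0.25, 0.75)), tolerance = 1e-12)
  set.seed(2)
  v <- rgamma(1000, 2)
  qn <- quantile_normalize(v)
  # rank invariance under strictly monotone transforms
  expect_equal(qn, quantile_normalize(exp(v)))
  expect_equal(mean(qn), 0, tolerance = 1e-8)
  expect_equal(var(qn), 1, tolerance = 0.01)
  # ties share averaged ranks; missing stays missing
  qt <- quantile_normalize(c(1, 1, 2, NA))
  expect_equal(qt[1], qt[2])
  expect_true(is.na(qt[4]))
  expect_error(quantile_normalize(rep(1, 5)), "constant")
  expect_error(quantile_normalize(c(1, NA, NA)), "non-missing")
})

test_that("mega_scan pools cohorts after per-cohort normalization", {
  set.seed(11)
  n <- 120
  g <- random_geno(20, n, seed = 11)
  x <- g$dosage[10, ]
  y <- 0.5 * x + rnorm(n)
  single <- assoc_scan(quantile_normalize(y), NULL, g, loco = FALSE)
  co <- list(y = y, geno = g)
  both <- mega_scan(list(co, co), loco = FALSE)
  # doubled n: same direction, smaller p at the causal SNP
  expect_equal(sign(both$beta[10]), sign(single$beta[10]))
  expect_lt(both$p[10], single$p[10])
  # binary traits skip the transform: identical scan to raw pass-through
  yb <- rbinom(n, 1, 0.4)
  mb <- mega_scan(list(list(y = yb, geno = g), list(y = yb, geno = g)),
                  binary = TRUE, loco = FALSE)
  expect_s3_class(mb, "assoc_table")
  # disjoint SNP sets error
  g2 <- random_geno(5, n, seed = 12, chrom = "2")
  expect_error(mega_scan(list(list(y = y, geno = g),
                              list(y = y, geno = g2)), loco = FALSE),
               "share no SNPs")
})

test_that("permutation threshold matches closed forms on independent SNPs", {
  set.seed(13)
  n <- 300
  y <- rnorm(n)
  # single SNP: threshold ~ -log10(0.05)
  g1 <- random_geno(1, n, seed = 13)
  t1 <- permutation_threshold(y, NULL, g1, n_perm = 400, seed = 3)$threshold
  expect_equal(t1, -log10(0.05), tolerance = 0.12)
  # m = 100 independent SNPs: Sidak -log10(1 - 0.95^(1/100)) ~ 3.29
  g100 <- random_geno(100, n, seed = 14)
  t100 <- permutation_threshold(y, NULL, g100, n_perm = 1000,
                                seed = 4)$threshold
  expect_equal(t100, -log10(1 - 0.95^(1 / 100)), tolerance = 0.3)
  # non-decreasing in the number of independent SNPs
  t10 <- permutation_threshold(y, NULL,
                               subset_genotypes(g100, snps = 1:10),
                               n_perm = 1000, seed = 4)$threshold
  expect_lte(t10, t100 + 0.05)
})
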