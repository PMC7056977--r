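bench <- ail_benchmark_loci()

test_that("locus replication classification matches the published benchmark", {
  disc <- data.frame(snp = bench$snp, p = bench$disc_p,
                     beta = bench$disc_beta, stringsAsFactors = FALSE)
  rep_ <- data.frame(snp = bench$snp, p = bench$rep_p,
                     beta = bench$rep_beta, stringsAsFactors = FALSE)
  cmp <- classify_replication(disc, rep_)
  i <- match("chr4.66414508", cmp$snp)
  expect_true(cmp$nominal_replicated[i])       # p 3.55e-3, same sign
  j <- match("chr15.67627183", cmp$snp)
  expect_false(cmp$same_sign[j])               # 0.30 vs -0.08
  k <- match("chr19.21812298", cmp$snp)
  expect_false(cmp$nominal_replicated[k])      # rep p 0.455
  # genomewide_replicated implies nominal_replicated
  cmp2 <- classify_replication(disc, rep_, genomewide_threshold = 1e-5)
  expect_true(all(!cmp2$genomewide_replicated | cmp2$nominal_replicated))
  expect_error(classify_replication(disc[-1, ], rep_,
                                    pairing = data.frame(
                                      disc_snp = disc$snp,
                                      rep_snp = disc$snp)),
               "chr4.66414508")
})

test_that("sign test counts strict sign agreement", {
  st <- sign_test(bench$disc_beta, bench$rep_beta)
  expect_equal(st$n_agree, 11L)
  expect_equal(st$n_total, 12L)
  expect_false(sign_test(0.3, -0.3)$n_agree == 1)
  expect_equal(sign_test(0, 1)$n_agree, 0L)    # zero counts as disagreement
  # all identical pairs: closed-form binomial p = 2 * 0.5^n
  st2 <- sign_test(rep(1, 8), rep(1, 8))
  expect_equal(st2$n_agree, 8L)
  expect_equal(st2$p_binomial, 2 * 0.5^8)
  expect_error(sign_test(numeric(0), numeric(0)), "empty")
})

test_that("conditional distribution follows the model's closed forms", {
  wc0 <- structure(list(sigma_g2 = 0, sigma_c1_2 = 0, sigma_c2_2 = 0),
                   class = "replication_fit")
  cd <- conditional_distribution(wc0, 7)
  expect_equal(cd$mean, 0)
  expect_equal(cd$variance, 1)
  wc3 <- structure(list(sigma_g2 = 3, sigma_c1_2 = 0, sigma_c2_2 = 0),
                   class = "replication_fit")
  cd3 <- conditional_distribution(wc3, 4)
  expect_equal(cd3$mean, 3)            # 3/4 * 4
  expect_equal(cd3$variance, 1.75)     # 4 - 9/4
  wcc <- structure(list(sigma_g2 = 3, sigma_c1_2 = 1, sigma_c2_2 = 2),
                   class = "replication_fit")
  cdc <- conditional_distribution(wcc, 5)
  expect_equal(cdc$mean, 3)            # 3/5 * 5
  expect_equal(cdc$variance, 4.2)      # 6 - 9/5
})

test_that("predicted and empirical replication rates match direct arithmetic", {
  wc3 <- structure(list(sigma_g2 = 3, sigma_c1_2 = 0, sigma_c2_2 = 0),
                   class = "replication_fit")
  pair1 <- data.frame(z_disc = 4, z_rep = 0)
  pr <- predicted_replication_rate(wc3, pair1, 1.96)
  expect_equal(pr, pnorm((3 - 1.96) / sqrt(1.75)) +
                 pnorm((-1.96 - 3) / sqrt(1.75)), tolerance = 1e-12)
  # sigma_g2 = 0: rate = 2 Phi(-threshold) regardless of s1
  wc0 <- structure(list(sigma_g2 = 0, sigma_c1_2 = 0, sigma_c2_2 = 0),
                   class = "replication_fit")
  expect_equal(predicted_replication_rate(wc0, data.frame(z_disc = c(2, 9)),
                                          2.5), 2 * pnorm(-2.5))
  # huge shared effect and huge discovery z -> rate ~ 1
  wcBig <- structure(list(sigma_g2 = 400, sigma_c1_2 = 0, sigma_c2_2 = 0),
                     class = "replication_fit")
  expect_gt(predicted_replication_rate(wcBig,
                                       data.frame(z_disc = c(30, 40)), 4), 0.999)
  # monotone non-decreasing in sigma_g2
  pair <- data.frame(z_disc = c(5, -6, 4.6))
  rates <- sapply(c(0.5, 2, 8, 32), function(sg) {
    f <- structure(list(sigma_g2 = sg, sigma_c1_2 = 0, sigma_c2_2 = 0),
                   class = "replication_fit")
    predicted_replication_rate(f, pair, 3)
  })
  expect_true(all(diff(rates) >= -1e-12))
  # empirical rate: direct counts
  p2 <- data.frame(z_disc = c(5, 5),
                   z_rep = qnorm(c(0.01, 0.5) / 2, lower.tail = FALSE))
  expect_equal(empirical_replication_rate(p2, 2), 0.5)  # Bonferroni 0.025
  expect_equal(empirical_replication_rate(
    data.frame(z_disc = 5, z_rep = 0), 1), 0)
  expect_equal(empirical_replication_rate(
    data.frame(z_disc = c(5, 5), z_rep = c(20, -20)), 2), 1)
  expect_error(empirical_replication_rate(p2[0, ], 0), "no discovery")
})

test_that("truncated MLE recovers variances; WC is nested in WC+C", {
  sp <- simulate_summary_pair(500, 16, 0, 0, t_disc = 4.5, seed = 1)
  wc <- fit_replication_model(sp, "WC")
  # 1-D grid oracle at 0.01 resolution in log space around the optimum
  grid <- exp(seq(log(4), log(64), by = 0.01))
  nll <- vapply(grid, function(sg)
    ailrep:::.rep_nll(c(sg, 0, 0), sp$z_disc, sp$z_rep, 4.5, TRUE),
    numeric(1))
  expect_equal(wc$sigma_g2, grid[which.min(nll)], tolerance = 0.02)
  # the continuous optimum is at least as good as the best grid point
  expect_gte(min(nll) - (-wc$loglik), -1e-6)
  expect_equal(wc$sigma_g2, 16, tolerance = 0.2 * 16)
  # nesting holds on heterogeneous data
  sph <- simulate_summary_pair(500, 4, 9, 9, t_disc = 3, seed = 2)
  wch <- fit_replication_model(sph, "WC")
  wcch <- fit_replication_model(sph, "WC+C")
  expect_gte(wcch$loglik, wch$loglik)
  expect_gt(wcch$loglik - wch$loglik, 1)   # truly better here
  # M = 1 violates the precondition
  expect_error(fit_replication_model(sp[1, ], "WC"), "at least two")
})

test_that("ascertainment correction removes the Winner's-Curse bias", {
  ests <- sapply(1:20, function(s) {
    sp <- simulate_summary_pair(300, 9, 0, 0, t_disc = 4, seed = 600 + s)
    c(corrected = fit_replication_model(sp, "WC")$sigma_g2,
      naive = fit_replication_model(sp, "WC",
                                    correct_ascertainment = FALSE)$sigma_g2)
  })
  expect_gt(mean(ests["naive", ]), 9 * 1.15)         # clearly inflated
  expect_equal(mean(ests["corrected", ]), 9, tolerance = 0.15 * 9)
})

test_that("parameter recovery at (25, 9, 9): median relative error <= 25%", {
  rel_err <- t(sapply(1:100, function(s) {
    sp <- simulate_summary_pair(500, 25, 9, 9, t_disc = 4.5,
                                seed = 1000 + s)
    f <- fit_replication_model(sp, "WC+C")
    abs(c(f$sigma_g2, f$sigma_c1_2, f$sigma_c2_2) - c(25, 9, 9)) /
      c(25, 9, 9)
  }))
  med <- apply(rel_err, 2, median)
  expect_true(all(med <= 0.25))
})

test_that("moment identities connect MLE and method of moments", {
  sp <- simulate_summary_pair(20000, 6, 2, 3, seed = 9)   # unascertained
  f <- fit_replication_model(sp, "WC+C")
  expect_equal(f$sigma_g2, cov(sp$z_disc, sp$z_rep), tolerance = 0.3)
  expect_equal(f$sigma_g2 + f$sigma_c1_2 + 1, var(sp$z_disc),
               tolerance = 0.3)
  expect_equal(f$sigma_g2 + f$sigma_c2_2 + 1, var(sp$z_rep),
               tolerance = 0.3)
})

test_that("high heterogeneity reproduces the WC vs WC+C contrast", {
  # strong study-specific effects: WC sees inflated sigma_g2 and predicts
  # near-total replication; WC+C tracks the (low) empirical rate
  sp <- simulate_summary_pair(400, 2, 20, 2, t_disc = 4.5, seed = 77)
  M <- nrow(sp)
  zb <- qnorm(0.05 / M / 2, lower.tail = FALSE)
  wc <- fit_replication_model(sp, "WC")
  wcc <- fit_replication_model(sp, "WC+C")
  emp <- empirical_replication_rate(sp, M)
  pred_wc <- predicted_replication_rate(wc, sp, zb)
  pred_wcc <- predicted_replication_rate(wcc, sp, zb)
  expect_lt(emp, 0.2)
  expect_gt(pred_wc, 5 * emp)
  expect_lt(abs(pred_wcc - emp), 0.15)
  expect_lt(pred_wcc, pred_wc - 0.3)
})

test_that("z_from_assoc matches p-value arithmetic and survives underflow", {
  expect_equal(z_from_assoc(-0.25, 0.05, 8.58e-8),
               -qnorm(8.58e-8 / 2, lower.tail = FALSE))
  expect_equal(z_from_assoc(0.2, 0.1, 1e-310), 2)   # fallback beta/se
  expect_equal(sign(z_from_assoc(c(1, -1), c(1, 1), c(0.05, 0.05))),
               c(1, -1))
})
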