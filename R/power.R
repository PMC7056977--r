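#' Analytic replication power
#'
#' Closed-form companion to the simulation: with true effect `beta` and
#' standard error `se`, the test statistic is N(beta/se, 1) and power is
#' P(|Z| > z_threshold).
#'
#' @param beta Effect size.
#' @param se Standard error (> 0).
#' @param alpha Two-sided significance level (used when `z_threshold` is
#'   missing).
#' @param z_threshold Critical value in z units; overrides `alpha`.
#' @return Power in [0, 1].
#' @examples
#' analytic_power(0.2, 0.1, alpha = 0.05)  # beta/se = 2 -> 0.516
#' @export
analytic_power <- function(beta, se, alpha = 0.05, z_threshold = NULL) {
  stopifnot(all(se > 0))
  zt <- z_threshold %||% stats::qnorm(1 - alpha / 2)
  m <- beta / se
  stats::pnorm(m - zt) + stats::pnorm(-zt - m)
}

#' Power configuration
#'
#' @param effect_sizes Effect-size grid in units of (quantile-normalized)
#'   trait SD per allele; the published design used 50 values.
#' @param n_reps Simulated scans per effect size (published design: 2,500;
#'   scale down for desk-scale runs).
#' @param gw_threshold Genome-wide threshold in -log10 p units.
#' @param nominal_alpha Nominal level (default 0.05).
#' @param seed Integer seed.
#' @return List of class `power_config`.
#' @export
power_config <- function(effect_sizes = seq(0, 0.5, length.out = 50),
                         n_reps = 2500, gw_threshold = 4.85,
                         nominal_alpha = 0.05, seed = 1L) {
  stopifnot(length(effect_sizes) >= 1, n_reps >= 1)
  if (gw_threshold < -log10(nominal_alpha)) {
    stop("genome-wide threshold is below the nominal threshold")
  }
  structure(list(effect_sizes = effect_sizes, n_reps = n_reps,
                 gw_threshold = gw_threshold,
                 nominal_alpha = nominal_alpha, seed = as.integer(seed)),
            class = "power_config")
}

#' Replication power by trait simulation under the null LMM fit
#'
#' For each effect size beta on the grid, traits are regenerated from the
#' null-model parameter estimates -- y = intercept + x beta + u + e with
#' u ~ MVN(0, sigma_g2_hat K) and e ~ MVN(0, sigma_e2_hat I) -- and the test
#' SNP is scanned with the mixed-model GLS (variance components held at the
#' null fit). Power is the fraction of replicates whose p beats each
#' threshold; the Monte-Carlo standard error is sqrt(p (1 - p) / n_reps).
#'
#' @param x Dosage vector at the test SNP.
#' @param K Relatedness matrix of the replication cohort.
#' @param null_fit A `null_fit` from the replication cohort's trait.
#' @param config A [power_config()].
#' @return data.frame of class `power_curve`: `effect_size`,
#'   `power_genomewide`, `power_nominal`, `mc_se_genomewide`,
#'   `mc_se_nominal`.
#' @export
replication_power <- function(x, K, null_fit, config = power_config()) {
  local_rng(config$seed)
  n <- length(x)
  x <- ifelse(is.na(x), mean(x, na.rm = TRUE), x)
  e <- null_fit$eigen %||% eigen(K, symmetric = TRUE)
  tr <- whiten_from(e, null_fit$lambda_ratio)
  W <- matrix(1, n, 1)
  Wt <- tr$w * crossprod(tr$U, W)
  xt <- tr$w * drop(crossprod(tr$U, x))
  Q <- qr.Q(qr(Wt))
  xr <- xt - drop(Q %*% crossprod(Q, xt))
  sxx <- sum(xr^2)
  df <- n - 2
  # polygenic draws: L z with L = U diag(sqrt(sigma_g2 * S))
  lamS <- pmax(e$values, 0)
  p_gw <- 10^(-config$gw_threshold)
  res <- lapply(config$effect_sizes, function(b) {
    Z <- matrix(stats::rnorm(n * config$n_reps), n, config$n_reps)
    U <- e$vectors %*% (sqrt(null_fit$sigma_g2 * lamS) * Z)
    E <- matrix(stats::rnorm(n * config$n_reps, 0,
                             sqrt(null_fit$sigma_e2)), n, config$n_reps)
    Y <- x * b + U + E      # intercept is absorbed by the covariate fit
    Yt <- tr$w * crossprod(tr$U, Y)
    Yr <- Yt - Q %*% crossprod(Q, Yt)
    sxy <- drop(crossprod(Yr, xr))
    beta <- sxy / sxx
    rss <- pmax(colSums(Yr^2) - beta^2 * sxx, 1e-300)
    tstat <- beta / sqrt(rss / df / sxx)
    p <- 2 * stats::pt(-abs(tstat), df)
    pw_gw <- mean(p < p_gw)
    pw_nom <- mean(p < config$nominal_alpha)
    c(pw_gw, pw_nom)
  })
  res <- do.call(rbind, res)
  out <- data.frame(effect_size = config$effect_sizes,
                    power_genomewide = res[, 1], power_nominal = res[, 2],
                    mc_se_genomewide =
                      sqrt(res[, 1] * (1 - res[, 1]) / config$n_reps),
                    mc_se_nominal =
                      sqrt(res[, 2] * (1 - res[, 2]) / config$n_reps))
  class(out) <- c("power_curve", "data.frame")
  out
}

whiten_from <- function(e, lambda) {
  list(U = e$vectors, w = 1 / sqrt(lambda * e$values + 1))
}
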