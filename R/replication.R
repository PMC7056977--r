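#' z-score from an association-table row
#'
#' Signed z derived from the two-sided p: sign(beta) * Phi^-1(1 - p/2),
#' falling back to beta/se when p underflows double precision.
#'
#' @param beta,se,p Effect estimate, its standard error, and the two-sided
#'   p-value.
#' @return Signed z-score(s).
#' @export
z_from_assoc <- function(beta, se, p) {
  z <- stats::qnorm(p / 2, lower.tail = FALSE)
  bad <- !is.finite(z) | p < 1e-300
  z[bad] <- abs(beta[bad] / se[bad])
  sign(beta) * z
}

#' Classify per-locus replication
#'
#' Pairs discovery and replication rows by SNP id (or accepts an explicit
#' pairing) and classifies each locus: `same_sign` (strict sign agreement of
#' the betas), `nominal_replicated` (replication p < 0.05 and same sign) and
#' `genomewide_replicated` (replication p below `genomewide_threshold` and
#' same sign).
#'
#' @param discovery,replication `assoc_table`-like data.frames with columns
#'   `snp`, `p`, `beta` (plus anything else, carried through).
#' @param genomewide_threshold Replication-cohort genome-wide p threshold.
#' @param pairing Optional two-column data.frame (`disc_snp`, `rep_snp`); by
#'   default loci are matched on identical SNP ids.
#' @return data.frame of class `locus_comparison`.
#' @export
classify_replication <- function(discovery, replication,
                                 genomewide_threshold = NULL,
                                 pairing = NULL) {
  if (is.null(pairing)) {
    pairing <- data.frame(disc_snp = discovery$snp,
                          rep_snp = discovery$snp,
                          stringsAsFactors = FALSE)
  }
  di <- match(pairing$disc_snp, discovery$snp)
  ri <- match(pairing$rep_snp, replication$snp)
  if (anyNA(di) || anyNA(ri)) {
    stop("unmatched locus id(s): ",
         paste(c(pairing$disc_snp[is.na(di)], pairing$rep_snp[is.na(ri)]),
               collapse = ", "))
  }
  same <- sign(discovery$beta[di]) == sign(replication$beta[ri]) &
    discovery$beta[di] != 0 & replication$beta[ri] != 0
  nom <- replication$p[ri] < 0.05 & same
  out <- data.frame(
    snp = pairing$disc_snp, rep_snp = pairing$rep_snp,
    disc_p = discovery$p[di], disc_beta = discovery$beta[di],
    rep_p = replication$p[ri], rep_beta = replication$beta[ri],
    same_sign = same, nominal_replicated = nom,
    genomewide_replicated = if (is.null(genomewide_threshold)) NA else
      nom & replication$p[ri] < genomewide_threshold,
    stringsAsFactors = FALSE)
  class(out) <- c("locus_comparison", "data.frame")
  out
}

#' Sign test on paired effect estimates
#'
#' Counts pairs whose betas have strictly the same sign (a zero beta counts
#' as disagreement) and optionally reports the exact two-sided binomial p
#' against probability 0.5.
#'
#' @param beta_disc,beta_rep Paired effect estimates.
#' @return List: `n_agree`, `n_total`, `p_binomial`.
#' @export
sign_test <- function(beta_disc, beta_rep) {
  if (!length(beta_disc)) stop("empty input")
  stopifnot(length(beta_disc) == length(beta_rep))
  agree <- sign(beta_disc) == sign(beta_rep) & beta_disc != 0 & beta_rep != 0
  n <- length(agree); k <- sum(agree)
  list(n_agree = k, n_total = n,
       p_binomial = stats::binom.test(k, n, 0.5)$p.value)
}

# Negative log-likelihood of a summary pair under the random-effects model.
# theta = (sigma_g2, sigma_c1_2, sigma_c2_2) on the raw scale. The discovery
# statistic contributes its marginal N(0, v1), truncated to |s1| > t_disc
# when correcting for ascertainment; the replication statistic contributes
# its conditional N((sigma_g2 / v1) s1, v2 - sigma_g2^2 / v1).
.rep_nll <- function(theta, s1, s2, t_disc, correct) {
  sg <- theta[1]; sc1 <- theta[2]; sc2 <- theta[3]
  v1 <- sg + sc1 + 1
  v2 <- sg + sc2 + 1
  cv <- v2 - sg^2 / v1
  ll <- stats::dnorm(s1, 0, sqrt(v1), log = TRUE) +
    stats::dnorm(s2, (sg / v1) * s1, sqrt(cv), log = TRUE)
  if (correct && !is.null(t_disc)) {
    ll <- ll - log(2 * stats::pnorm(-t_disc / sqrt(v1)))
  }
  -sum(ll)
}

#' Fit the Winner's-Curse replication models
#'
#' Maximum likelihood for the random-effects models of paired
#' discovery/replication z-scores. Both models share a genetic effect
#' lambda ~ N(0, sigma_g2) entering both statistics; the WC+C model adds
#' independent study-specific effects delta^(i) ~ N(0, sigma_ci^2). The
#' likelihood conditions on discovery ascertainment (|s1| > t_disc) through
#' the truncated marginal of s1; replication statistics are not treated as
#' ascertained. Optimization is L-BFGS-B on the log-variance scale with
#' multiple starts (including moment-based ones); for WC+C the exact WC
#' optimum embedded at sigma_c = 0 is also evaluated so the nested-model
#' log-likelihood ordering holds exactly.
#'
#' @param pair A `summary_pair` (columns `z_disc`, `z_rep`; attribute or
#'   argument `t_disc`).
#' @param model `"WC"` or `"WC+C"`.
#' @param t_disc Ascertainment threshold in z units; defaults to the pair's
#'   attribute; `NULL` disables the truncation term.
#' @param correct_ascertainment Set `FALSE` to fit the untruncated
#'   likelihood (used to demonstrate the Winner's-Curse bias).
#' @return List of class `replication_fit`: `model`, `sigma_g2`,
#'   `sigma_c1_2`, `sigma_c2_2`, `loglik`, `n_variants`, `t_disc`.
#' @export
fit_replication_model <- function(pair, model = c("WC", "WC+C"),
                                  t_disc = attr(pair, "t_disc"),
                                  correct_ascertainment = TRUE) {
  model <- match.arg(model)
  s1 <- pair$z_disc; s2 <- pair$z_rep
  if (length(s1) < 2) {
    stop("estimation of the model parameters requires at least two variants")
  }
  lo <- -12; hi <- 12
  # moment starts: Cov ~ sigma_g2, Var - 1 - sigma_g2 ~ sigma_c2
  cv <- max(stats::cov(s1, s2), 0.01)
  m_c1 <- max(stats::var(s1) - 1 - cv, 0.01)
  m_c2 <- max(stats::var(s2) - 1 - cv, 0.01)

  nll_wc <- function(lg) .rep_nll(c(exp(lg), 0, 0), s1, s2, t_disc,
                                  correct_ascertainment)
  # 1-D problem: golden-section/Brent on the log-variance scale
  owc <- stats::optimize(nll_wc, c(lo, hi), tol = 1e-10)
  cand <- rbind(c(lo, nll_wc(lo)), c(owc$minimum, owc$objective),
                c(hi, nll_wc(hi)))
  best <- cand[which.min(cand[, 2]), ]
  wc <- list(model = "WC", sigma_g2 = exp(best[1]), sigma_c1_2 = 0,
             sigma_c2_2 = 0, loglik = -best[2],
             n_variants = length(s1), t_disc = t_disc)
  if (model == "WC") {
    class(wc) <- "replication_fit"
    return(wc)
  }

  nll_wcc <- function(lth) .rep_nll(exp(lth), s1, s2, t_disc,
                                    correct_ascertainment)
  starts <- list(log(c(cv, m_c1, m_c2)),
                 c(log(wc$sigma_g2), lo, lo),
                 log(c(0.1, 0.1, 0.1)), log(c(10, 10, 10)),
                 log(c(1, 5, 5)))
  starts <- lapply(starts, function(s) pmin(pmax(s, lo), hi))
  fits <- lapply(starts, function(s0) {
    tryCatch(stats::optim(s0, nll_wcc, method = "L-BFGS-B",
                          lower = lo, upper = hi,
                          control = list(factr = 1e4)),
             error = function(e) list(par = s0, value = Inf))
  })
  vals <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.min(vals)]]
  theta <- exp(best$par)
  ll <- -best$value
  # exact boundary candidate: the WC optimum embedded in WC+C
  ll_b <- -.rep_nll(c(wc$sigma_g2, 0, 0), s1, s2, t_disc,
                    correct_ascertainment)
  if (ll_b >= ll) {
    theta <- c(wc$sigma_g2, 0, 0)
    ll <- ll_b
  }
  out <- list(model = "WC+C", sigma_g2 = theta[1], sigma_c1_2 = theta[2],
              sigma_c2_2 = theta[3], loglik = ll,
              n_variants = length(s1), t_disc = t_disc)
  class(out) <- "replication_fit"
  out
}

#' @export
print.replication_fit <- function(x, ...) {
  cat(sprintf(
    "%s fit: sigma_g2 = %.3f, sigma_c1_2 = %.3f, sigma_c2_2 = %.3f\n",
    x$model, x$sigma_g2, x$sigma_c1_2, x$sigma_c2_2))
  cat(sprintf("loglik = %.3f over %d variants (t_disc = %s)\n",
              x$loglik, x$n_variants,
              if (is.null(x$t_disc)) "none" else format(x$t_disc)))
  invisible(x)
}

#' Conditional distribution of the replication statistic
#'
#' Under the fitted model, s2 | s1 is normal with mean (sigma_g2 / v1) s1
#' and variance v2 - sigma_g2^2 / v1, where v_i = sigma_g2 + sigma_ci^2 + 1.
#'
#' @param fit A `replication_fit`.
#' @param s1 Discovery z-score(s).
#' @return List: `mean` (same length as `s1`), `variance` (scalar).
#' @export
conditional_distribution <- function(fit, s1) {
  v1 <- fit$sigma_g2 + fit$sigma_c1_2 + 1
  v2 <- fit$sigma_g2 + fit$sigma_c2_2 + 1
  list(mean = (fit$sigma_g2 / v1) * s1,
       variance = v2 - fit$sigma_g2^2 / v1)
}

#' Model-predicted replication rate
#'
#' Mean over the discovery-significant variants of the probability that the
#' replication statistic exceeds `rep_threshold` in magnitude under its
#' conditional distribution given the observed discovery statistic;
#' `sign_consistent = TRUE` counts only the tail on the discovery side.
#'
#' @param fit A `replication_fit`.
#' @param pair The `summary_pair` the fit was computed from.
#' @param rep_threshold Replication significance threshold in z units
#'   (e.g. `qnorm(1 - 0.05 / M / 2)` for Bonferroni).
#' @param sign_consistent Require the replication effect to share the
#'   discovery sign (default `FALSE`, two-sided).
#' @return The predicted rate in [0, 1].
#' @export
predicted_replication_rate <- function(fit, pair, rep_threshold,
                                       sign_consistent = FALSE) {
  stopifnot(rep_threshold > 0)
  cd <- conditional_distribution(fit, pair$z_disc)
  sdv <- sqrt(cd$variance)
  up <- stats::pnorm((cd$mean - rep_threshold) / sdv)
  dn <- stats::pnorm((-rep_threshold - cd$mean) / sdv)
  pr <- if (sign_consistent) ifelse(pair$z_disc >= 0, up, dn) else up + dn
  mean(pr)
}

#' Empirical replication rate
#'
#' Fraction of the M discovery-significant variants whose two-sided
#' replication p falls below the Bonferroni-corrected threshold
#' `rep_alpha / M`.
#'
#' @param pair A `summary_pair` restricted to the discovery-significant
#'   variants.
#' @param M Number of discovery-significant variants (defaults to
#'   `nrow(pair)`).
#' @param rep_alpha Family-wise alpha (default 0.05).
#' @return The empirical rate.
#' @export
empirical_replication_rate <- function(pair, M = nrow(pair),
                                       rep_alpha = 0.05) {
  if (M == 0) stop("no discovery-significant variants")
  p_rep <- 2 * stats::pnorm(-abs(pair$z_rep))
  sum(p_rep < rep_alpha / M) / M
}

#' Full two-cohort replication assessment
#'
#' Runs the whole pipeline on two association tables: selects
#' discovery-significant variants, derives z-scores, fits WC and WC+C,
#' and reports empirical plus predicted replication rates.
#'
#' @param discovery,replication `assoc_table`s sharing SNP ids.
#' @param disc_threshold Discovery genome-wide threshold in -log10 p units.
#' @param rep_alpha Replication family-wise alpha (default 0.05).
#' @param sign_consistent Passed to [predicted_replication_rate()].
#' @return List of class `replication_assessment`: `M`, `t_disc`,
#'   `rep_threshold_z`, `empirical_rate`, `wc`, `wcc`, `predicted_rate_wc`,
#'   `predicted_rate_wcc`, `pair`.
#' @export
assess_replication <- function(discovery, replication, disc_threshold,
                               rep_alpha = 0.05, sign_consistent = FALSE) {
  shared <- intersect(discovery$snp, replication$snp)
  d <- discovery[match(shared, discovery$snp), ]
  r <- replication[match(shared, replication$snp), ]
  sig <- which(d$neg_log10_p > disc_threshold)
  M <- length(sig)
  if (M < 2) stop("fewer than two discovery-significant variants (M = ",
                  M, ")")
  p_disc <- 10^(-disc_threshold)
  t_disc <- stats::qnorm(p_disc / 2, lower.tail = FALSE)
  pair <- data.frame(
    variant_id = d$snp[sig],
    z_disc = z_from_assoc(d$beta[sig], d$se[sig], d$p[sig]),
    z_rep = z_from_assoc(r$beta[sig], r$se[sig], r$p[sig]),
    stringsAsFactors = FALSE)
  attr(pair, "t_disc") <- t_disc
  class(pair) <- c("summary_pair", "data.frame")
  wc <- fit_replication_model(pair, "WC")
  wcc <- fit_replication_model(pair, "WC+C")
  zb <- stats::qnorm(rep_alpha / M / 2, lower.tail = FALSE)
  out <- list(M = M, t_disc = t_disc, rep_threshold_z = zb,
              empirical_rate = empirical_replication_rate(pair, M, rep_alpha),
              wc = wc, wcc = wcc,
              predicted_rate_wc =
                predicted_replication_rate(wc, pair, zb, sign_consistent),
              predicted_rate_wcc =
                predicted_replication_rate(wcc, pair, zb, sign_consistent),
              pair = pair)
  class(out) <- "replication_assessment"
  out
}

#' @export
print.replication_assessment <- function(x, ...) {
  cat(sprintf("M = %d discovery-significant variants (t_disc = %.2f)\n",
              x$M, x$t_disc))
  cat(sprintf("empirical replication rate: %.3f\n", x$empirical_rate))
  cat(sprintf("predicted rate  WC : %.3f (sigma_g2 = %.2f)\n",
              x$predicted_rate_wc, x$wc$sigma_g2))
  cat(sprintf("predicted rate WC+C: %.3f (sigma_g2 = %.2f, sigma_c1_2 = %.2f, sigma_c2_2 = %.2f)\n",
              x$predicted_rate_wcc, x$wcc$sigma_g2, x$wcc$sigma_c1_2,
              x$wcc$sigma_c2_2))
  invisible(x)
}
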