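#' Specify a simulated trait
#'
#' @param trait_type `"quantitative"`, `"albino"` or `"agouti"`.
#' @param causal_snps Character vector of causal SNP ids (quantitative
#'   traits; for coat traits the single proxy SNP).
#' @param beta Per-allele effect sizes, trait SD units, one per causal SNP.
#' @param sigma_g2 Polygenic (kinship-structured) variance.
#' @param sigma_e2 Residual variance.
#' @param alpha Covariate coefficients (named by covariate column).
#' @param study_effect_sd SD of a cohort-specific random shift added to each
#'   causal effect, emulating study-specific heterogeneity; 0 disables it.
#' @param seed Integer seed.
#' @return A list of class `trait_sim_spec`.
#' @export
trait_sim_spec <- function(trait_type = c("quantitative", "albino", "agouti"),
                           causal_snps = character(), beta = numeric(),
                           sigma_g2 = 0.3, sigma_e2 = 0.7,
                           alpha = NULL, study_effect_sd = 0, seed = 1L) {
  trait_type <- match.arg(trait_type)
  stopifnot(sigma_g2 >= 0, sigma_e2 >= 0, study_effect_sd >= 0,
            length(causal_snps) == length(beta))
  structure(list(trait_type = trait_type, causal_snps = causal_snps,
                 beta = beta, sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                 alpha = alpha, study_effect_sd = study_effect_sd,
                 seed = as.integer(seed)),
            class = "trait_sim_spec")
}

#' Simulate phenotypes on a genotyped cohort
#'
#' Quantitative traits follow the mixed model y = W alpha + sum_j x_j beta_j
#' + u + e with u ~ MVN(0, sigma_g^2 K) and e ~ MVN(0, sigma_e^2 I). Coat
#' traits are Mendelian functions of their proxy SNP: albino individuals are
#' homozygous for the recessive (strain-B) allele at the Tyr-proxy SNP;
#' agouti is dominant for the strain-B allele at its proxy SNP and is coded
#' `NA` for albino individuals (epistatic masking).
#'
#' @param geno A `genotype_matrix` for the cohort.
#' @param kinship Relatedness matrix used as the covariance scale of the
#'   polygenic term (e.g. `2 * kinship_from_pedigree(...)` restricted to the
#'   cohort, or a GRM).
#' @param spec A [trait_sim_spec()].
#' @param covariates Optional data.frame of covariates aligned to
#'   `geno$samples`; columns named in `spec$alpha` contribute `W alpha`.
#' @param tyr_proxy,agouti_proxy SNP ids of the coat-trait proxies; required
#'   for `trait_type = "albino"` (and `"agouti"`, which needs both so the
#'   albino mask can be applied).
#' @return A data.frame with columns `individual_id` and `value`.
#' @export
simulate_phenotypes <- function(geno, kinship, spec, covariates = NULL,
                                tyr_proxy = NULL, agouti_proxy = NULL) {
  ids <- geno$samples
  n <- length(ids)

  if (spec$trait_type == "albino") {
    if (is.null(tyr_proxy)) stop("tyr_proxy SNP id required")
    d <- geno$dosage[match(tyr_proxy, geno$map$snp), ]
    return(data.frame(individual_id = ids, value = as.numeric(d == 2),
                      stringsAsFactors = FALSE))
  }
  if (spec$trait_type == "agouti") {
    if (is.null(agouti_proxy) || is.null(tyr_proxy)) {
      stop("agouti_proxy and tyr_proxy SNP ids required")
    }
    da <- geno$dosage[match(agouti_proxy, geno$map$snp), ]
    albino <- geno$dosage[match(tyr_proxy, geno$map$snp), ] == 2
    v <- as.numeric(da >= 1)      # tan dominant over black
    v[albino] <- NA               # white masks agouti
    return(data.frame(individual_id = ids, value = v,
                      stringsAsFactors = FALSE))
  }

  local_rng(spec$seed)
  y <- numeric(n)
  if (!is.null(spec$alpha) && !is.null(covariates)) {
    W <- as.matrix(covariates[, names(spec$alpha), drop = FALSE])
    y <- y + drop(W %*% unlist(spec$alpha))
  }
  if (length(spec$causal_snps)) {
    ix <- match(spec$causal_snps, geno$map$snp)
    if (anyNA(ix)) stop("causal SNP(s) not in the SNP map")
    b <- spec$beta
    if (spec$study_effect_sd > 0) {
      b <- b + stats::rnorm(length(b), 0, spec$study_effect_sd)
    }
    X <- t(geno$dosage[ix, , drop = FALSE])
    X[is.na(X)] <- mean(X, na.rm = TRUE)
    y <- y + drop(X %*% b)
  }
  if (spec$sigma_g2 > 0) {
    K <- kinship[ids, ids]
    y <- y + drop(mvn_sample(1, spec$sigma_g2 * K))
  }
  if (spec$sigma_e2 > 0) y <- y + stats::rnorm(n, 0, sqrt(spec$sigma_e2))
  data.frame(individual_id = ids, value = y, stringsAsFactors = FALSE)
}

# Draw n MVN(0, Sigma) vectors (columns) via eigendecomposition; errors if
# Sigma is not PSD within tolerance.
mvn_sample <- function(n, Sigma, tol = 1e-8) {
  e <- eigen(Sigma, symmetric = TRUE)
  lam <- e$values
  if (min(lam) < -tol * max(abs(lam))) {
    stop("covariance (kinship) matrix is not positive semi-definite")
  }
  lam[lam < 0] <- 0
  L <- e$vectors %*% (sqrt(lam) * t(e$vectors))
  L %*% matrix(stats::rnorm(nrow(Sigma) * n), ncol = n)
}

#' Simulate paired discovery/replication z-scores
#'
#' Generative model: per variant a shared genetic effect lambda ~ N(0,
#' sigma_g2) and independent study-specific effects delta1 ~ N(0, sigma_c1_2),
#' delta2 ~ N(0, sigma_c2_2); observed statistics s1 = lambda + delta1 + e1,
#' s2 = lambda + delta2 + e2 with unit-variance noise. With `t_disc` set, the
#' returned variants are an ascertained set: rejection sampling keeps drawing
#' until `n_variants` satisfy |s1| > t_disc.
#'
#' @param n_variants Number of variants to return (>= 1).
#' @param sigma_g2,sigma_c1_2,sigma_c2_2 Variance components (>= 0).
#' @param t_disc Discovery ascertainment threshold in z units, or `NULL` for
#'   an unascertained sample.
#' @param seed Integer seed.
#' @return A data.frame of class `summary_pair` with columns `variant_id`,
#'   `z_disc`, `z_rep` and attribute `t_disc`.
#' @export
simulate_summary_pair <- function(n_variants, sigma_g2, sigma_c1_2 = 0,
                                  sigma_c2_2 = 0, t_disc = NULL, seed = 1L) {
  stopifnot(n_variants >= 1, sigma_g2 >= 0, sigma_c1_2 >= 0, sigma_c2_2 >= 0)
  local_rng(seed)
  draw <- function(nd) {
    lam <- stats::rnorm(nd, 0, sqrt(sigma_g2))
    s1 <- lam + stats::rnorm(nd, 0, sqrt(sigma_c1_2)) + stats::rnorm(nd)
    s2 <- lam + stats::rnorm(nd, 0, sqrt(sigma_c2_2)) + stats::rnorm(nd)
    cbind(s1, s2)
  }
  if (is.null(t_disc)) {
    z <- draw(n_variants)
  } else {
    v1 <- sigma_g2 + sigma_c1_2 + 1
    p_pass <- 2 * stats::pnorm(-t_disc / sqrt(v1))
    z <- matrix(numeric(0), 0, 2)
    while (nrow(z) < n_variants) {
      batch <- max(100L, ceiling(1.5 * (n_variants - nrow(z)) /
                                   max(p_pass, 1e-12)))
      cand <- draw(batch)
      z <- rbind(z, cand[abs(cand[, 1]) > t_disc, , drop = FALSE])
    }
    z <- z[seq_len(n_variants), , drop = FALSE]
  }
  out <- data.frame(variant_id = paste0("v", seq_len(n_variants)),
                    z_disc = z[, 1], z_rep = z[, 2],
                    stringsAsFactors = FALSE)
  attr(out, "t_disc") <- t_disc
  class(out) <- c("summary_pair", "data.frame")
  out
}
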