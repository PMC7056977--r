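#' Genetic relatedness matrix
#'
#' Computes a GRM from dosages, optionally excluding one chromosome
#' (leave-one-chromosome-out, which keeps the tested chromosome out of the
#' polygenic term and avoids proximal contamination). Missing dosages are
#' mean-imputed per SNP. Two conventions are offered: `"centered"` (GEMMA's
#' default: SNPs centered, G = Xc Xc' / m) and `"standardized"` (SNPs
#' centered and scaled to unit variance, mean diagonal ~ 1).
#'
#' @param geno A `genotype_matrix`.
#' @param exclude_chrom Chromosome id to leave out, or `NULL`.
#' @param type GRM convention.
#' @return Symmetric n x n matrix with sample ids as dimnames.
#' @export
compute_grm <- function(geno, exclude_chrom = NULL,
                        type = c("centered", "standardized")) {
  type <- match.arg(type)
  keep <- rep(TRUE, nrow(geno$dosage))
  if (!is.null(exclude_chrom)) {
    keep <- geno$map$chrom != normalize_chrom(exclude_chrom)
  }
  if (sum(keep) < 2) stop("fewer than 2 usable SNPs for the GRM")
  X <- t(geno$dosage[keep, , drop = FALSE])   # samples x SNPs
  X <- impute_mean(X)
  X <- scale(X, center = TRUE, scale = FALSE)
  v <- apply(X, 2, stats::var)
  poly <- v > 0
  X <- X[, poly, drop = FALSE]
  if (type == "standardized") X <- sweep(X, 2, sqrt(v[poly]), "/")
  G <- tcrossprod(X) / ncol(X)
  dimnames(G) <- list(geno$samples, geno$samples)
  G
}

# column-wise mean imputation of a samples x SNPs matrix
impute_mean <- function(X) {
  if (!anyNA(X)) return(X)
  mu <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  X[idx] <- mu[idx[, 2]]
  X
}

#' REML fit of the null mixed model
#'
#' Fits y = W alpha + u + e with u ~ MVN(0, sigma_g^2 K), e ~ MVN(0,
#' sigma_e^2 I) by restricted maximum likelihood. A single eigendecomposition
#' of K reduces the profiled REML criterion to a 1-D optimization over the
#' variance ratio lambda = sigma_g^2 / sigma_e^2, searched on the log10
#' scale over [-5, 5] with endpoint checks, so boundary fits are returned
#' without failure.
#'
#' @param y Trait vector (no missing values).
#' @param W Covariate (fixed-effect) matrix; `NULL` for intercept only.
#' @param K Relatedness matrix (or its precomputed eigendecomposition from
#'   `eigen(K, symmetric = TRUE)`).
#' @return List of class `null_fit`: `lambda_ratio`, `sigma_g2`, `sigma_e2`,
#'   `h2`, `loglik_reml`, `alpha` (GLS fixed-effect estimates), plus the
#'   eigendecomposition reused by the scan.
#' @export
fit_null <- function(y, W = NULL, K) {
  if (any(!is.finite(y))) {
    stop("non-finite trait values for sample(s): ",
         paste(which(!is.finite(y)), collapse = ", "))
  }
  n <- length(y)
  W <- check_covar(W, n)
  if (n < ncol(W) + 2) stop("too few samples for the model")
  e <- if (is.list(K) && !is.null(K$vectors)) K else eigen(K, symmetric = TRUE)
  Ut_y <- drop(crossprod(e$vectors, y))
  Ut_W <- crossprod(e$vectors, W)
  ldet_WtW <- determinant(crossprod(W), logarithm = TRUE)$modulus

  crit <- function(l10) -reml_ll(10^l10, e$values, Ut_y, Ut_W, ldet_WtW)
  opt <- stats::optimize(crit, c(-5, 5), tol = 1e-8)
  # endpoint checks; prefer the smallest lambda when the profile is flat
  # (K proportional to I leaves the ratio unidentified)
  cand <- rbind(c(-5, crit(-5)), c(opt$minimum, opt$objective),
                c(5, crit(5)))
  best <- cand[which(cand[, 2] <= min(cand[, 2]) + 1e-7)[1], ]
  lambda <- 10^best[1]

  d <- lambda * e$values + 1
  w <- 1 / d
  A <- crossprod(Ut_W, Ut_W * w)
  alpha <- solve(A, crossprod(Ut_W, Ut_y * w))
  r <- Ut_y - drop(Ut_W %*% alpha)
  sigma_e2 <- sum(w * r^2) / (n - ncol(W))
  fit <- list(lambda_ratio = lambda, sigma_g2 = lambda * sigma_e2,
              sigma_e2 = sigma_e2, h2 = lambda / (1 + lambda),
              loglik_reml = -best[2], alpha = drop(alpha),
              eigen = e, n = n)
  class(fit) <- "null_fit"
  fit
}

# Profiled REML log-likelihood at variance ratio lambda.
reml_ll <- function(lambda, S, Ut_y, Ut_W, ldet_WtW) {
  n <- length(Ut_y); c <- ncol(Ut_W)
  d <- lambda * S + 1
  w <- 1 / d
  A <- crossprod(Ut_W, Ut_W * w)
  alpha <- tryCatch(solve(A, crossprod(Ut_W, Ut_y * w)),
                    error = function(e) NULL)
  if (is.null(alpha)) return(-Inf)
  r <- Ut_y - drop(Ut_W %*% alpha)
  rss <- sum(w * r^2)
  nc <- n - c
  sigma_e2 <- rss / nc
  ldet_A <- determinant(A, logarithm = TRUE)$modulus
  -0.5 * (nc * log(2 * pi * sigma_e2) + nc + sum(log(d)) +
            as.numeric(ldet_A) - as.numeric(ldet_WtW))
}

check_covar <- function(W, n) {
  if (is.null(W)) return(matrix(1, n, 1, dimnames = list(NULL, "intercept")))
  W <- as.matrix(W)
  if (nrow(W) != n) stop("covariate rows must match trait length")
  if (!any(apply(W, 2, function(col) all(col == col[1])))) {
    W <- cbind(intercept = 1, W)
  }
  qrW <- qr(W)
  if (qrW$rank < ncol(W)) W <- W[, qrW$pivot[seq_len(qrW$rank)], drop = FALSE]
  W
}

#' Linear mixed model association scan
#'
#' Per-SNP generalized least squares with the variance components fixed at
#' the null REML fit of the matching GRM (the EMMAX-style approximation:
#' variance components are not re-optimized per SNP). With `loco = TRUE` a
#' leave-one-chromosome-out GRM and null fit are computed per chromosome.
#' The test statistic is beta/se with per-SNP residual variance and a
#' t(n - c - 1) reference, which reduces exactly to ordinary least squares
#' when K is the identity (or absent).
#'
#' @param y Trait vector.
#' @param W Covariate matrix or `NULL` (intercept only).
#' @param geno A `genotype_matrix`.
#' @param loco Use leave-one-chromosome-out GRMs (default `TRUE`).
#' @param K Relatedness matrix for `loco = FALSE`; `NULL` there means an
#'   identity (plain linear model).
#' @param grm_type GRM convention passed to [compute_grm()].
#' @return data.frame of class `assoc_table`: `chrom`, `snp`, `pos`, `n`,
#'   `af`, `beta`, `se`, `p`, `neg_log10_p`, `monomorphic`.
#' @export
assoc_scan <- function(y, W = NULL, geno, loco = TRUE, K = NULL,
                       grm_type = "centered") {
  n <- length(y)
  if (n != length(geno$samples)) stop("trait length must match samples")
  W <- check_covar(W, n)
  if (!loco) {
    tr <- if (!is.null(K)) whiten(fit_null(y, W, K)) else NULL
    res <- scan_core(y, W, t(geno$dosage), tr)
    tab <- cbind(chrom = geno$map$chrom, snp = geno$map$snp,
                 pos = geno$map$pos, res, stringsAsFactors = FALSE)
  } else {
    chroms <- unique(geno$map$chrom)
    out <- vector("list", length(chroms))
    for (i in seq_along(chroms)) {
      ch <- chroms[i]
      on_ch <- geno$map$chrom == ch
      Kc <- compute_grm(geno, exclude_chrom = ch, type = grm_type)
      tr <- whiten(fit_null(y, W, Kc))
      res <- scan_core(y, W, t(geno$dosage[on_ch, , drop = FALSE]), tr)
      out[[i]] <- cbind(chrom = ch, snp = geno$map$snp[on_ch],
                        pos = geno$map$pos[on_ch], res,
                        stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, out)
    tab <- tab[match(geno$map$snp, tab$snp), , drop = FALSE]
  }
  rownames(tab) <- NULL
  class(tab) <- c("assoc_table", "data.frame")
  tab
}

# Whitening transform from a null fit: t(x) -> D^{-1/2} U' x.
whiten <- function(fit) {
  d <- fit$lambda_ratio * fit$eigen$values + 1
  list(U = fit$eigen$vectors, w = 1 / sqrt(d))
}

# GLS/OLS core: X is samples x SNPs; tr NULL means identity covariance.
scan_core <- function(y, W, X, tr = NULL) {
  n <- length(y)
  X <- impute_mean(X)
  af <- colMeans(X) / 2
  mono <- apply(X, 2, stats::var) == 0
  if (!is.null(tr)) {
    yt <- tr$w * drop(crossprod(tr$U, y))
    Wt <- tr$w * crossprod(tr$U, W)
    Xt <- tr$w * crossprod(tr$U, X)
  } else {
    yt <- y; Wt <- W; Xt <- X
  }
  Q <- qr.Q(qr(Wt))
  yr <- yt - drop(Q %*% crossprod(Q, yt))
  Xr <- Xt - Q %*% crossprod(Q, Xt)
  sxx <- colSums(Xr^2)
  sxy <- drop(crossprod(Xr, yr))
  syy <- sum(yr^2)
  df <- n - ncol(W) - 1
  beta <- ifelse(sxx > 1e-12, sxy / sxx, 0)
  rss <- pmax(syy - beta^2 * sxx, 0)
  se <- sqrt(rss / df / sxx)
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df)
  bad <- mono | sxx <= 1e-12
  beta[bad] <- 0; se[bad] <- NA_real_; p[bad] <- 1
  data.frame(n = n, af = af, beta = beta, se = se, p = p,
             neg_log10_p = -log10(p), monomorphic = bad,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank-based inverse normal transform
#'
#' Maps values to normal quantiles Phi^-1((rank - 0.5) / n) where n counts
#' non-missing values; ties get averaged ranks, missing values stay missing.
#'
#' @param values Numeric vector.
#' @return Transformed vector of the same length.
#' @examples
#' quantile_normalize(c(3, 10))  # -0.674, 0.674
#' @export
quantile_normalize <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2) stop("need at least 2 non-missing values")
  v <- values[ok]
  if (max(v) == min(v)) stop("transform undefined for a constant vector")
  out <- rep(NA_real_, length(values))
  out[ok] <- stats::qnorm((rank(v, ties.method = "average") - 0.5) / length(v))
  out
}

#' Permutation genome-wide significance threshold
#'
#' Naive permutation: the trait vector is shuffled against the fixed
#' (covariate, genotype) rows, covariates are re-fit in every scan, and the
#' genome-wide maximum -log10 p is recorded per permutation; the threshold
#' is the requested quantile of these maxima. Variance components are held
#' at the unpermuted null fit (permutation destroys the polygenic structure,
#' so re-fitting them per permutation changes nothing at null).
#'
#' @param y,W,geno As in [assoc_scan()].
#' @param K Relatedness matrix or `NULL` for identity.
#' @param n_perm Number of permutations (>= 100; the convention is 1,000).
#' @param quantile_ Quantile of the max distribution (default 0.95).
#' @param seed Integer seed.
#' @return List: `threshold` (in -log10 p units), `maxima` (per-permutation
#'   genome-wide maxima).
#' @export
permutation_threshold <- function(y, W = NULL, geno, K = NULL,
                                  n_perm = 1000, quantile_ = 0.95,
                                  seed = 1L) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  local_rng(seed)
  n <- length(y)
  W <- check_covar(W, n)
  tr <- if (!is.null(K)) whiten(fit_null(y, W, K)) else NULL
  X <- impute_mean(t(geno$dosage))
  if (!is.null(tr)) {
    Wt <- tr$w * crossprod(tr$U, W)
    Xt <- tr$w * crossprod(tr$U, X)
  } else {
    Wt <- W; Xt <- X
  }
  Q <- qr.Q(qr(Wt))
  Xr <- Xt - Q %*% crossprod(Q, Xt)
  sxx <- colSums(Xr^2)
  ok <- sxx > 1e-12
  df <- n - ncol(W) - 1
  maxima <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    yp <- y[sample.int(n)]
    yt <- if (!is.null(tr)) tr$w * drop(crossprod(tr$U, yp)) else yp
    yr <- yt - drop(Q %*% crossprod(Q, yt))
    sxy <- drop(crossprod(Xr[, ok, drop = FALSE], yr))
    beta <- sxy / sxx[ok]
    rss <- pmax(sum(yr^2) - beta^2 * sxx[ok], 1e-300)
    tstat <- beta / sqrt(rss / df / sxx[ok])
    pmin_ <- 2 * stats::pt(-max(abs(tstat)), df)
    maxima[b] <- -log10(pmin_)
  }
  list(threshold = unname(stats::quantile(maxima, quantile_)),
       maxima = maxima)
}

#' Mega-analysis scan across cohorts
#'
#' Pools individual-level data: each cohort's continuous trait is quantile
#' normalized separately (binary traits are passed through unchanged), the
#' samples are concatenated, a cohort indicator is added to the covariates,
#' and the scan runs on the SNPs shared by all cohorts.
#'
#' @param cohorts A list; each element a list with components `y`, `W`
#'   (optional) and `geno`.
#' @param binary Is the trait binary (skip the normalization)?
#' @param loco,grm_type Passed to [assoc_scan()].
#' @return An `assoc_table` over the shared SNP set.
#' @export
mega_scan <- function(cohorts, binary = FALSE, loco = TRUE,
                      grm_type = "centered") {
  stopifnot(length(cohorts) >= 2)
  shared <- Reduce(intersect, lapply(cohorts, function(co) co$geno$map$snp))
  if (!length(shared)) stop("cohorts share no SNPs")
  ys <- list(); Ws <- list(); dosages <- list(); samples <- character()
  for (i in seq_along(cohorts)) {
    co <- cohorts[[i]]
    g <- subset_genotypes(co$geno, snps = shared)
    y <- if (binary) co$y else quantile_normalize(co$y)
    ys[[i]] <- y
    Wi <- check_covar(co$W, length(y))
    Ws[[i]] <- Wi
    dosages[[i]] <- g$dosage
    samples <- c(samples, paste0("c", i, "_", g$samples))
    if (i == 1) map <- g$map
  }
  # align covariate columns by name (intercept always first)
  allcols <- unique(unlist(lapply(Ws, colnames)))
  Wall <- do.call(rbind, lapply(Ws, function(Wi) {
    M <- matrix(0, nrow(Wi), length(allcols), dimnames = list(NULL, allcols))
    M[, colnames(Wi)] <- Wi
    M
  }))
  cohort_id <- rep(seq_along(cohorts), vapply(ys, length, 1L))
  if (length(cohorts) > 1) {
    ind <- stats::model.matrix(~ factor(cohort_id))[, -1, drop = FALSE]
    colnames(ind) <- paste0("cohort", seq_len(ncol(ind)) + 1)
    Wall <- cbind(Wall, ind)
  }
  geno_all <- genotype_matrix(do.call(cbind, dosages), map = map,
                              samples = samples)
  assoc_scan(unlist(ys), Wall, geno_all, loco = loco, grm_type = grm_type)
}
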