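#' Composite LD between two SNPs
#'
#' Squared Pearson correlation of the dosage vectors (composite LD; no
#' phasing needed).
#'
#' @param geno A `genotype_matrix`.
#' @param snp_i,snp_j SNP ids.
#' @return r^2 in [0, 1].
#' @export
ld_r2 <- function(geno, snp_i, snp_j) {
  ix <- match(c(snp_i, snp_j), geno$map$snp)
  if (anyNA(ix)) stop("unknown SNP id(s)")
  a <- geno$dosage[ix[1], ]; b <- geno$dosage[ix[2], ]
  ok <- !is.na(a) & !is.na(b)
  if (stats::var(a[ok]) == 0 || stats::var(b[ok]) == 0) {
    stop("monomorphic SNP: LD undefined")
  }
  stats::cor(a[ok], b[ok])^2
}

#' LD decay curve
#'
#' Mean r^2 between allele-frequency-matched SNP pairs (|MAF_i - MAF_j| <
#' `maf_match`) within `max_dist` bp on the same chromosome, binned by
#' physical distance.
#'
#' @param geno A `genotype_matrix`.
#' @param max_dist Maximum pair distance in bp (default 100,000).
#' @param maf_match Maximum MAF difference for a pair to qualify.
#' @param n_bins Number of equal-width distance bins.
#' @return data.frame: `dist_lo`, `dist_hi`, `mean_r2`, `n_pairs`. Empty
#'   (with a warning) when no pairs qualify.
#' @export
ld_decay <- function(geno, max_dist = 1e5, maf_match = 0.05, n_bins = 10) {
  af <- allele_freq(geno)
  maf <- pmin(af, 1 - af)
  poly <- maf > 0
  breaks <- seq(0, max_dist, length.out = n_bins + 1)
  d_all <- numeric(0); r2_all <- numeric(0)
  for (ch in unique(geno$map$chrom)) {
    ix <- which(geno$map$chrom == ch & poly)
    if (length(ix) < 2) next
    pos <- geno$map$pos[ix]
    pairs <- which(outer(pos, pos, function(a, b) abs(a - b)) <= max_dist &
                     abs(outer(maf[ix], maf[ix], "-")) < maf_match &
                     upper.tri(diag(length(ix))), arr.ind = TRUE)
    if (!nrow(pairs)) next
    D <- t(geno$dosage[ix, , drop = FALSE])
    r2 <- vapply(seq_len(nrow(pairs)), function(k) {
      stats::cor(D[, pairs[k, 1]], D[, pairs[k, 2]],
                 use = "complete.obs")^2
    }, numeric(1))
    d_all <- c(d_all, abs(pos[pairs[, 1]] - pos[pairs[, 2]]))
    r2_all <- c(r2_all, r2)
  }
  if (!length(d_all)) {
    warning("no qualifying SNP pairs for the LD decay curve")
    return(data.frame(dist_lo = numeric(0), dist_hi = numeric(0),
                      mean_r2 = numeric(0), n_pairs = integer(0)))
  }
  bin <- cut(d_all, breaks, include.lowest = TRUE, labels = FALSE)
  agg <- tapply(r2_all, bin, mean)
  cnt <- tapply(r2_all, bin, length)
  used <- as.integer(names(agg))
  data.frame(dist_lo = breaks[used], dist_hi = breaks[used + 1],
             mean_r2 = as.numeric(agg), n_pairs = as.integer(cnt),
             row.names = NULL)
}

#' LD-based clumping of significant SNPs
#'
#' Greedy lead-locus selection: the most significant unassigned SNP passing
#' `p_threshold` becomes a lead, and every unassigned significant SNP within
#' `window_kb` of it (PLINK `--clump-kb` semantics: +/- window_kb) and with
#' r^2 >= `r2` joins its clump; repeat until no significant SNP is left.
#' Ties on p are broken by ascending position then lexicographic id.
#'
#' @param assoc An `assoc_table`.
#' @param geno Matching `genotype_matrix`.
#' @param p_threshold Significance threshold on p.
#' @param r2 LD threshold for clump membership (default 0.1).
#' @param window_kb Half-window in kb (default 12,150).
#' @return data.frame of class `lead_loci`: one row per lead with
#'   `lead_snp`, `chrom`, `pos`, `p`, `n_members`, `span_bp`, `member_ids`
#'   (comma-separated).
#' @export
clump <- function(assoc, geno, p_threshold, r2 = 0.1, window_kb = 12150) {
  sig <- assoc[assoc$p < p_threshold & !is.na(assoc$p), , drop = FALSE]
  empty <- data.frame(lead_snp = character(0), chrom = character(0),
                      pos = integer(0), p = numeric(0),
                      n_members = integer(0), span_bp = integer(0),
                      member_ids = character(0), stringsAsFactors = FALSE)
  class(empty) <- c("lead_loci", "data.frame")
  if (!nrow(sig)) return(empty)
  if (!all(sig$snp %in% geno$map$snp)) {
    stop("association table and genotypes must share SNP ids")
  }
  sig <- sig[order(sig$p, sig$pos, sig$snp), , drop = FALSE]
  assigned <- rep(FALSE, nrow(sig))
  D <- t(impute_mean(t(geno$dosage[match(sig$snp, geno$map$snp), ,
                                   drop = FALSE])))
  out <- list()
  while (any(!assigned)) {
    lead <- which(!assigned)[1]
    cand <- which(!assigned)
    same_ch <- sig$chrom[cand] == sig$chrom[lead]
    near <- abs(sig$pos[cand] - sig$pos[lead]) <= window_kb * 1000
    r2v <- rep(0, length(cand))
    chk <- same_ch & near
    if (any(chk)) {
      r2v[chk] <- drop(stats::cor(D[lead, ], t(D[cand[chk], , drop = FALSE])))^2
      r2v[is.na(r2v)] <- 0
    }
    member <- cand == lead | (chk & r2v >= r2)
    members <- cand[member]
    assigned[members] <- TRUE
    out[[length(out) + 1]] <- data.frame(
      lead_snp = sig$snp[lead], chrom = sig$chrom[lead],
      pos = sig$pos[lead], p = sig$p[lead],
      n_members = length(members),
      span_bp = max(sig$pos[members]) - min(sig$pos[members]),
      member_ids = paste(sig$snp[members], collapse = ","),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("lead_loci", "data.frame")
  res
}

#' Credible set around a lead SNP
#'
#' Bayesian credible set from summary z-scores: the region is restricted to
#' SNPs in LD r^2 >= `r2_min` with the lead; each SNP's posterior is
#' proportional to exp(z^2 / 2) (equal-prior Bayes-factor approximation,
#' log-sum-exp stabilized), and the included set is the smallest
#' descending-posterior prefix with cumulative posterior >= `coverage`.
#' `method = "wakefield"` uses the approximate Bayes factor with prior
#' effect variance `prior_w` instead.
#'
#' @param z Named vector of region z-scores (names = SNP ids).
#' @param geno A `genotype_matrix` covering the region SNPs.
#' @param lead Lead SNP id (must be in `z`).
#' @param r2_min LD threshold with the lead (default 0.8).
#' @param coverage Target coverage (default 0.99).
#' @param method `"exp_z2"` (default) or `"wakefield"`.
#' @param prior_w Wakefield prior variance (default 0.04).
#' @param se Standard errors (required for `"wakefield"`).
#' @return data.frame of class `credible_set`: `snp`, `z`, `posterior`,
#'   `in_set`, ordered by descending posterior; attributes `span_bp`,
#'   `coverage`.
#' @export
credible_set <- function(z, geno, lead, r2_min = 0.8, coverage = 0.99,
                         method = c("exp_z2", "wakefield"), prior_w = 0.04,
                         se = NULL) {
  method <- match.arg(method)
  if (!lead %in% names(z)) stop("lead SNP absent from the region z-scores")
  keep <- vapply(names(z), function(s) {
    s == lead || ld_r2(geno, lead, s) >= r2_min
  }, logical(1))
  z <- z[keep]
  if (method == "exp_z2") {
    logbf <- z^2 / 2
  } else {
    if (is.null(se)) stop("wakefield method needs standard errors")
    se <- se[keep]
    v <- se^2
    logbf <- 0.5 * log(v / (v + prior_w)) + z^2 / 2 * prior_w / (v + prior_w)
  }
  post <- exp(logbf - (max(logbf) + log(sum(exp(logbf - max(logbf))))))
  ord <- order(post, decreasing = TRUE)
  cum <- cumsum(post[ord])
  n_in <- which(cum >= coverage)[1]
  in_set <- seq_along(ord) <= n_in
  out <- data.frame(snp = names(z)[ord], z = z[ord], posterior = post[ord],
                    in_set = in_set, row.names = NULL,
                    stringsAsFactors = FALSE)
  pos <- geno$map$pos[match(out$snp[out$in_set], geno$map$snp)]
  attr(out, "span_bp") <- diff(range(pos))
  attr(out, "coverage") <- coverage
  class(out) <- c("credible_set", "data.frame")
  out
}

#' Conditional association rescan
#'
#' Re-runs the scan with the dosages of the conditioning SNPs appended to
#' the covariates; conditioning SNPs that are monomorphic or collinear with
#' the existing covariates are dropped with a warning.
#'
#' @param y,W,geno,loco,K Passed to [assoc_scan()].
#' @param condition_on SNP ids to condition on.
#' @return An `assoc_table` over the remaining SNPs.
#' @export
conditional_scan <- function(y, W = NULL, geno, condition_on,
                             loco = TRUE, K = NULL) {
  ix <- match(condition_on, geno$map$snp)
  if (anyNA(ix)) stop("conditioning SNP(s) not in the SNP map")
  W <- check_covar(W, length(y))
  Xc <- t(impute_mean(t(geno$dosage[ix, , drop = FALSE])))
  keep <- logical(length(ix))
  for (k in seq_along(ix)) {
    cand <- cbind(W, t(Xc[k, , drop = FALSE]))
    if (qr(cand)$rank == ncol(cand)) {
      W <- cand
      colnames(W)[ncol(W)] <- condition_on[k]
      keep[k] <- TRUE
    } else {
      warning("conditioning SNP ", condition_on[k],
              " is collinear with covariates; dropped")
    }
  }
  rest <- setdiff(geno$map$snp, condition_on)
  assoc_scan(y, W, subset_genotypes(geno, snps = rest), loco = loco, K = K)
}
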