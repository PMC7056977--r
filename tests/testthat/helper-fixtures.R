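# Shared in-code fixtures; everything is generated at test time.

# Small AIL world reused across tests: 6-generation pedigree, 2 chromosomes.
ail_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ped <- build_ail_pedigree(20, 6, 4, seed = 7)
      map <- simulate_genetic_map(n_chrom = 2, snps_per_chrom = 40)
      geno <- gene_drop(ped, map, seed = 3)
      kin <- kinship_from_pedigree(ped)
      cache <<- list(ped = ped, map = map, geno = geno, kin = kin)
    }
    cache
  }
})

# genotype_matrix from a dosage matrix on one chromosome, evenly spaced
toy_geno <- function(dosage, chrom = "1", spacing = 1e4) {
  m <- nrow(dosage)
  map <- genetic_map(chrom = rep(chrom, m),
                     pos = seq(1, by = spacing, length.out = m),
                     cm = seq(0, by = spacing * 0.56e-6 * 100, length.out = m))
  genotype_matrix(dosage, map, samples = paste0("s", seq_len(ncol(dosage))))
}

# iid binomial dosages: m SNPs x n samples at allele frequency p
random_geno <- function(m, n, p = 0.5, seed = 1, chrom = "1") {
  set.seed(seed)
  toy_geno(matrix(rbinom(m * n, 2, p), m, n), chrom = chrom)
}

# Independent HWE chi-square oracle: explicit expected-count arithmetic,
# written against the textbook multinomial formula.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  p_hat <- (n_AA + n_Aa / 2) / n
  if (p_hat %in% c(0, 1)) return(1)
  e <- c(AA = n * p_hat^2, Aa = n * 2 * p_hat * (1 - p_hat),
         aa = n * (1 - p_hat)^2)
  x2 <- (n_AA - e[1])^2 / e[1] + (n_Aa - e[2])^2 / e[2] +
    (n_aa - e[3])^2 / e[3]
  unname(stats::pchisq(x2, 1, lower.tail = FALSE))
}

# Dense GLS oracle for the mixed-model scan: whiten with the Cholesky root
# of V = sigma_g2 K + sigma_e2 I from the null fit, then delegate to lm().
gls_oracle <- function(y, W, x, K, fit) {
  V <- fit$sigma_g2 * K + fit$sigma_e2 * diag(length(y))
  Li <- solve(t(chol(V)))
  yt <- drop(Li %*% y)
  At <- Li %*% cbind(W, x)
  sm <- summary(stats::lm(yt ~ At - 1))$coefficients
  k <- nrow(sm)
  c(beta = sm[k, 1], se = sm[k, 2], p = sm[k, 4])
}

# Dense REML log-likelihood oracle evaluated on a lambda grid.
reml_grid_oracle <- function(y, W, K, lambdas) {
  n <- length(y); c <- ncol(W)
  vapply(lambdas, function(l) {
    V <- l * K + diag(n)
    Vi <- solve(V)
    B <- t(W) %*% Vi %*% W
    P <- Vi - Vi %*% W %*% solve(B) %*% t(W) %*% Vi
    s2 <- drop(t(y) %*% P %*% y) / (n - c)
    -0.5 * ((n - c) * log(2 * pi * s2) + (n - c) +
              determinant(V)$modulus + determinant(B)$modulus -
              determinant(t(W) %*% W)$modulus)
  }, numeric(1))
}

# Literal restatement of the greedy clumping definition, computing every
# pairwise r2 up front and re-scanning the assignment from scratch.
clump_oracle <- function(assoc, geno, p_threshold, r2, window_kb) {
  sig <- assoc[assoc$p < p_threshold, ]
  sig <- sig[order(sig$p, sig$pos, sig$snp), ]
  R2 <- suppressWarnings(stats::cor(t(geno$dosage))^2)
  rownames(R2) <- colnames(R2) <- geno$map$snp
  left <- sig$snp
  leads <- list()
  while (length(left)) {
    lead <- left[1]
    li <- match(lead, sig$snp)
    mem <- lead
    for (s in setdiff(left, lead)) {
      si <- match(s, sig$snp)
      if (sig$chrom[si] == sig$chrom[li] &&
          abs(sig$pos[si] - sig$pos[li]) <= window_kb * 1000 &&
          R2[lead, s] >= r2) mem <- c(mem, s)
    }
    leads[[lead]] <- sort(mem)
    left <- setdiff(left, mem)
  }
  leads
}
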