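#' Flag heterozygosity outliers
#'
#' Computes the autosomal heterozygosity proportion per sample (fraction of
#' non-missing calls with dosage 1, hard calls assumed) and flags samples
#' more than `k_sd` standard deviations from the across-sample mean.
#'
#' @param geno A `genotype_matrix`; chromosomes named "X"/"Y" are excluded.
#' @param k_sd Cutoff in SD units (default 3, the conventional screen).
#' @return data.frame: `individual_id`, `het`, `het_outlier`.
#' @export
heterozygosity_filter <- function(geno, k_sd = 3) {
  if (length(geno$samples) < 3) stop("need at least 3 samples")
  auto <- !(geno$map$chrom %in% c("X", "Y"))
  d <- geno$dosage[auto, , drop = FALSE]
  n_called <- colSums(!is.na(d))
  if (any(n_called == 0)) {
    stop("sample(s) with all genotypes missing: ",
         paste(geno$samples[n_called == 0], collapse = ", "))
  }
  het <- colSums(d == 1, na.rm = TRUE) / n_called
  mu <- mean(het); s <- stats::sd(het)
  flag <- abs(het - mu) > k_sd * s
  if (k_sd == 0) flag <- het != mu
  data.frame(individual_id = geno$samples, het = het, het_outlier = flag,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Infer sex from the X/Y read ratio
#'
#' @param read_ratio Per-sample ratio of reads mapped to X vs Y (>= 0).
#' @param recorded_sex Character vector, "male"/"female".
#' @param female_interval,male_interval Disjoint (lo, hi) intervals for the
#'   ratio; the defaults are published 95% CIs for a GBS AIL panel
#'   (females 196.84-214.3, males 2.13-2.18).
#' @return data.frame: `read_ratio`, `recorded_sex`, `inferred_sex`
#'   ("male"/"female"/NA), `sex_mismatch`.
#' @export
sex_check <- function(read_ratio, recorded_sex,
                      female_interval = c(196.84, 214.3),
                      male_interval = c(2.13, 2.18)) {
  stopifnot(female_interval[1] < female_interval[2],
            male_interval[1] < male_interval[2])
  if (male_interval[2] > female_interval[1] &&
      female_interval[2] > male_interval[1]) {
    stop("sex intervals must be disjoint")
  }
  if (any(read_ratio < 0)) stop("negative read ratio")
  inferred <- rep(NA_character_, length(read_ratio))
  inferred[read_ratio >= female_interval[1] &
             read_ratio <= female_interval[2]] <- "female"
  inferred[read_ratio >= male_interval[1] &
             read_ratio <= male_interval[2]] <- "male"
  data.frame(read_ratio = read_ratio, recorded_sex = recorded_sex,
             inferred_sex = inferred,
             sex_mismatch = is.na(inferred) | inferred != recorded_sex,
             stringsAsFactors = FALSE)
}

#' Flag pedigree/genotype relatedness discordance
#'
#' Compares expected relatedness from the pedigree (2 x kinship, numerator
#' relatedness) against realized relatedness from a genotype-derived GRM and
#' returns sample pairs whose absolute difference exceeds `delta_max`.
#' Diagonals are excluded.
#'
#' @param pedigree_kinship Kinship matrix (coefficients, diagonal 0.5(1+f)).
#' @param grm Genetic relatedness matrix over the same samples.
#' @param delta_max Flagging threshold on the relatedness scale
#'   (default 0.10).
#' @return data.frame of flagged pairs: `id1`, `id2`, `expected`, `observed`,
#'   `delta`.
#' @export
kinship_concordance <- function(pedigree_kinship, grm, delta_max = 0.10) {
  ids <- rownames(pedigree_kinship)
  if (is.null(ids) || is.null(rownames(grm)) ||
      !setequal(ids, rownames(grm))) {
    stop("kinship matrices must cover the same samples")
  }
  grm <- grm[ids, ids]
  expected <- 2 * pedigree_kinship
  delta <- abs(expected - grm)
  ut <- upper.tri(delta)
  hit <- which(ut & delta > delta_max, arr.ind = TRUE)
  data.frame(id1 = ids[hit[, 1]], id2 = ids[hit[, 2]],
             expected = expected[hit], observed = grm[hit],
             delta = delta[hit], stringsAsFactors = FALSE)
}

#' Flag coat-color/genotype discordance at the albino locus
#'
#' Albinism is recessive: a recorded albino must be homozygous for the
#' albino-linked haplotype at the markers flanking Tyr, and a non-albino
#' must not be. A sample's flanking-haplotype dosage is the mean dosage over
#' the flanking markers; homozygosity is mean dosage > 1.5, heterozygosity
#' or less disqualifies albinism.
#'
#' @param albino Per-sample recorded albino code (1 = white, 0 = non-white,
#'   NA = unknown).
#' @param geno A `genotype_matrix`.
#' @param flanking_snps Ids of the markers flanking the Tyr locus.
#' @return data.frame: `individual_id`, `albino`, `flank_dosage`,
#'   `coat_discordant` (NA when untestable).
#' @export
coat_color_concordance <- function(albino, geno, flanking_snps) {
  ix <- match(flanking_snps, geno$map$snp)
  if (anyNA(ix)) stop("flanking marker(s) absent from the SNP map")
  d <- geno$dosage[ix, , drop = FALSE]
  flank <- colMeans(d, na.rm = TRUE)
  untestable <- colSums(!is.na(d)) == 0
  homo <- flank > 1.5
  disc <- ifelse(is.na(albino), NA,
                 ifelse(albino == 1, !homo, homo))
  disc[untestable] <- NA
  data.frame(individual_id = geno$samples, albino = albino,
             flank_dosage = ifelse(untestable, NA, flank),
             coat_discordant = disc, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Chi-square test of Hardy-Weinberg equilibrium
#'
#' 1-df chi-square comparing observed genotype counts to the p^2 : 2pq : q^2
#' expectation with the allele frequency estimated from the counts; no
#' continuity correction. Monomorphic input returns p = 1 by convention (the
#' MAF filter removes such SNPs anyway).
#'
#' @param n_AA,n_Aa,n_aa Genotype counts.
#' @return The p-value.
#' @examples
#' hwe_test(30, 40, 30)  # chi-square 4, p ~ 0.0455
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("need at least one genotype")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p == 0 || p == 1) return(1)
  q <- 1 - p
  expd <- n * c(p^2, 2 * p * q, q^2)
  chi2 <- sum((c(n_AA, n_Aa, n_aa) - expd)^2 / expd)
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' SNP-level quality control
#'
#' Applies the GBS panel filters: minor allele frequency >= `maf_min`,
#' Hardy-Weinberg chi-square p >= `hwe_min`, and, when a per-SNP imputation
#' quality score is present, dosage r^2 > `r2_min`. Soft-call dosages are
#' rounded to hard calls for the HWE count table. SNPs with HWE p within
#' `hwe_near_factor` x `hwe_min` of the threshold are flagged `hwe_near` as
#' candidates for the dubious-SNP review.
#'
#' @param geno A `genotype_matrix` (optionally carrying `dosage_r2`).
#' @param maf_min,hwe_min,r2_min Filter thresholds (defaults 0.1, 1e-6, 0.9).
#' @param hwe_near_factor Proximity factor for the `hwe_near` flag.
#' @return data.frame of class `snp_qc_report`: `snp`, `maf`, `hwe_p`,
#'   `dosage_r2`, `hwe_near`, `kept`.
#' @export
snp_filter <- function(geno, maf_min = 0.1, hwe_min = 1e-6, r2_min = 0.9,
                       hwe_near_factor = 10) {
  hard <- round(geno$dosage)
  n_AA <- rowSums(hard == 0, na.rm = TRUE)
  n_Aa <- rowSums(hard == 1, na.rm = TRUE)
  n_aa <- rowSums(hard == 2, na.rm = TRUE)
  hwe_p <- mapply(hwe_test, n_AA, n_Aa, n_aa)
  af <- allele_freq(geno)
  maf <- pmin(af, 1 - af)
  kept <- maf >= maf_min & hwe_p >= hwe_min
  r2 <- geno$dosage_r2
  if (!is.null(r2)) kept <- kept & r2 > r2_min
  out <- data.frame(snp = geno$map$snp, maf = maf, hwe_p = hwe_p,
                    dosage_r2 = if (is.null(r2)) NA_real_ else r2,
                    hwe_near = kept & hwe_p < hwe_near_factor * hwe_min,
                    kept = kept, row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("snp_qc_report", "data.frame")
  out
}

#' Combined sample QC report
#'
#' Runs the four sample-level screens (heterozygosity, sex ratio, kinship
#' concordance, coat-color concordance) and combines their flags; a sample
#' is kept iff no flag is set.
#'
#' @param geno A `genotype_matrix`.
#' @param read_ratio,recorded_sex Inputs to [sex_check()] (optional).
#' @param pedigree_kinship,grm Inputs to [kinship_concordance()] (optional).
#' @param albino,flanking_snps Inputs to [coat_color_concordance()]
#'   (optional).
#' @param k_sd,delta_max,female_interval,male_interval Screen parameters.
#' @return data.frame of class `sample_qc_report` with per-sample flags and
#'   `kept`.
#' @export
sample_qc <- function(geno, read_ratio = NULL, recorded_sex = NULL,
                      pedigree_kinship = NULL, grm = NULL,
                      albino = NULL, flanking_snps = NULL,
                      k_sd = 3, delta_max = 0.10,
                      female_interval = c(196.84, 214.3),
                      male_interval = c(2.13, 2.18)) {
  rep_ <- heterozygosity_filter(geno, k_sd = k_sd)
  rep_$sex_mismatch <- FALSE
  if (!is.null(read_ratio)) {
    sx <- sex_check(read_ratio, recorded_sex, female_interval, male_interval)
    rep_$sex_mismatch <- sx$sex_mismatch
    rep_$inferred_sex <- sx$inferred_sex
  }
  rep_$kinship_discordant <- FALSE
  if (!is.null(pedigree_kinship) && !is.null(grm)) {
    pairs <- kinship_concordance(pedigree_kinship, grm, delta_max)
    bad <- unique(c(pairs$id1, pairs$id2))
    rep_$kinship_discordant <- rep_$individual_id %in% bad
  }
  rep_$coat_discordant <- FALSE
  if (!is.null(albino) && !is.null(flanking_snps)) {
    cc <- coat_color_concordance(albino, geno, flanking_snps)
    rep_$coat_discordant <- !is.na(cc$coat_discordant) & cc$coat_discordant
  }
  rep_$kept <- !(rep_$het_outlier | rep_$sex_mismatch |
                   rep_$kinship_discordant | rep_$coat_discordant)
  class(rep_) <- c("sample_qc_report", "data.frame")
  rep_
}
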