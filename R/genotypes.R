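#' Construct a genetic map
#'
#' A genetic map is a `data.frame` with one row per SNP: `snp` (id), `chrom`
#' (string, "chr" prefixes stripped), `pos` (bp, 1-based), `cm` (genetic
#' position), `a1`/`a2` (reference/alternate allele labels). Within each
#' chromosome the genetic position must be non-decreasing in physical
#' position.
#'
#' @param chrom,pos,cm Per-SNP chromosome, physical and genetic positions.
#' @param snp SNP ids; default `"<chrom>.<pos>"`, the AIL naming convention.
#' @param a1,a2 Allele labels (defaults "A", "B": the two founder strains).
#' @return A `data.frame` of class `genetic_map`.
#' @export
genetic_map <- function(chrom, pos, cm, snp = NULL, a1 = "A", a2 = "B") {
  chrom <- normalize_chrom(chrom)
  if (is.null(snp)) snp <- paste0("chr", chrom, ".", pos)
  map <- data.frame(snp = as.character(snp), chrom = chrom,
                    pos = as.integer(pos), cm = as.numeric(cm),
                    a1 = a1, a2 = a2, stringsAsFactors = FALSE)
  ord <- order(map$chrom, map$pos)
  map <- map[ord, , drop = FALSE]
  for (ch in unique(map$chrom)) {
    cmv <- map$cm[map$chrom == ch]
    if (!anyNA(cmv) && is.unsorted(cmv)) {
      stop("genetic position must be non-decreasing in physical position ",
           "on chromosome ", ch)
    }
  }
  rownames(map) <- NULL
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Simulate an AIL-like SNP map
#'
#' Uniformly spaced SNPs with a constant cM/Mb rate, the simplest map
#' consistent with a dense genotyping-by-sequencing panel.
#'
#' @param n_chrom Number of chromosomes (labelled "1", "2", ...).
#' @param snps_per_chrom SNPs per chromosome.
#' @param chrom_length_bp Chromosome length in bp.
#' @param cm_per_mb Recombination rate (mouse genome average ~ 0.5-0.6).
#' @return A `genetic_map`.
#' @export
simulate_genetic_map <- function(n_chrom = 2, snps_per_chrom = 50,
                                 chrom_length_bp = 1e8, cm_per_mb = 0.56) {
  pos <- round(seq(1, chrom_length_bp, length.out = snps_per_chrom))
  genetic_map(
    chrom = rep(as.character(seq_len(n_chrom)), each = snps_per_chrom),
    pos = rep(pos, n_chrom),
    cm = rep(pos / 1e6 * cm_per_mb, n_chrom)
  )
}

#' Construct a genotype matrix
#'
#' @param dosage Numeric matrix, SNPs in rows, samples in columns; values in
#'   [0, 2] (count of the `a2` allele), `NA` allowed.
#' @param map A `genetic_map` with one row per row of `dosage`.
#' @param samples Sample ids, one per column.
#' @param dosage_r2 Optional per-SNP imputation quality score, passed through
#'   to the SNP QC filter.
#' @return A list of class `genotype_matrix` with elements `dosage`, `map`,
#'   `samples`, `dosage_r2`.
#' @export
genotype_matrix <- function(dosage, map, samples, dosage_r2 = NULL) {
  dosage <- as.matrix(dosage)
  if (nrow(dosage) != nrow(map)) stop("dosage rows must match map rows")
  if (ncol(dosage) != length(samples)) {
    stop("dosage columns must match sample list")
  }
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  if (!is.null(dosage_r2) && length(dosage_r2) != nrow(map)) {
    stop("dosage_r2 must have one value per SNP")
  }
  dimnames(dosage) <- list(map$snp, samples)
  structure(list(dosage = dosage, map = map,
                 samples = as.character(samples), dosage_r2 = dosage_r2),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "SNPs x", length(x$samples),
      "samples on", length(unique(x$map$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param geno A `genotype_matrix`.
#' @param snps SNP ids or logical/integer index over SNPs (`NULL` = all).
#' @param samples Sample ids or index (`NULL` = all).
#' @return The subsetted `genotype_matrix`.
#' @export
subset_genotypes <- function(geno, snps = NULL, samples = NULL) {
  i <- if (is.null(snps)) seq_len(nrow(geno$dosage)) else
    if (is.character(snps)) match(snps, geno$map$snp) else which_idx(snps, nrow(geno$dosage))
  if (anyNA(i)) stop("unknown SNP id(s)")
  j <- if (is.null(samples)) seq_along(geno$samples) else
    if (is.character(samples)) match(samples, geno$samples) else which_idx(samples, length(geno$samples))
  if (anyNA(j)) stop("unknown sample id(s)")
  genotype_matrix(geno$dosage[i, j, drop = FALSE],
                  map = geno$map[i, , drop = FALSE],
                  samples = geno$samples[j],
                  dosage_r2 = geno$dosage_r2[i])
}

which_idx <- function(x, n) if (is.logical(x)) which(x) else as.integer(x)

#' Per-SNP alternate-allele frequency
#'
#' @param geno A `genotype_matrix`.
#' @return Numeric vector, mean dosage / 2 per SNP (missing values dropped).
#' @export
allele_freq <- function(geno) {
  rowMeans(geno$dosage, na.rm = TRUE) / 2
}

#' Drop genotypes down a pedigree
#'
#' Gene-dropping simulation: the two generation-0 founders are assigned
#' opposite homozygous genotypes at every SNP (two inbred strains), and each
#' transmitted gamete is formed by recombining the parent's two haplotypes
#' with crossovers drawn independently in each marker interval under the
#' Haldane (no-interference) map function, r = (1 - exp(-2 d_cM / 100)) / 2.
#'
#' @param ped An `ail_pedigree`; generation 0 must contain exactly two
#'   founders.
#' @param map A `genetic_map`; every SNP needs a finite `cm`.
#' @param seed Integer seed.
#' @return A `genotype_matrix` of dosages in {0, 1, 2} (count of the strain-B
#'   allele `a2`) for every pedigree member.
#' @export
gene_drop <- function(ped, map, seed = 1L) {
  validate_pedigree(ped)
  if (nrow(map) < 1) stop("map must contain at least one SNP")
  if (anyNA(map$cm)) stop("SNP with missing genetic position")
  rng <- local_rng(seed)

  ord <- order(ped$generation)
  ped <- ped[ord, , drop = FALSE]
  ids <- ped$individual_id
  n <- length(ids)
  m <- nrow(map)
  founders <- which(ped$generation == 0L)
  if (length(founders) != 2L) {
    stop("gene_drop requires exactly two generation-0 founders")
  }

  # per-chromosome interval recombination fractions (Haldane)
  chroms <- unique(map$chrom)
  chrom_idx <- lapply(chroms, function(ch) which(map$chrom == ch))
  rec <- lapply(chrom_idx, function(ix) {
    d <- diff(map$cm[ix])
    0.5 * (1 - exp(-2 * d / 100))
  })

  hap1 <- matrix(0L, m, n); hap2 <- matrix(0L, m, n)
  colnames(hap1) <- colnames(hap2) <- ids
  # founder A: allele 0 on both haplotypes; founder B: allele 1
  hap1[, founders[2]] <- 1L
  hap2[, founders[2]] <- 1L

  idx <- stats::setNames(seq_len(n), ids)
  for (i in seq_len(n)) {
    if (ped$generation[i] == 0L) next
    p <- idx[[ped$sire_id[i]]]
    q <- idx[[ped$dam_id[i]]]
    hap1[, i] <- .meiosis(hap1[, p], hap2[, p], chrom_idx, rec)
    hap2[, i] <- .meiosis(hap1[, q], hap2[, q], chrom_idx, rec)
  }

  genotype_matrix(hap1 + hap2, map = map, samples = ids)
}

# One gamete: per chromosome pick a random starting haplotype, then switch
# between the parent's haplotypes with the interval recombination fractions.
.meiosis <- function(hA, hB, chrom_idx, rec) {
  out <- integer(length(hA))
  for (k in seq_along(chrom_idx)) {
    ix <- chrom_idx[[k]]
    r <- rec[[k]]
    start <- sample.int(2L, 1L) - 1L
    switches <- if (length(r)) as.integer(stats::runif(length(r)) < r) else integer(0)
    state <- (start + cumsum(c(0L, switches))) %% 2L
    out[ix] <- ifelse(state == 0L, hA[ix], hB[ix])
  }
  out
}
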