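#' Published two-cohort lead-locus replication benchmark
#'
#' Twelve lead loci from a published LG/J x SM/J AIL replication study
#' (body weight, the two Mendelian coat-color traits, and locomotor
#' activity), with discovery and replication association statistics
#' (p, allele frequency, beta, se) in both directions between the F34 and
#' F39-43 cohorts. Used as a fixed benchmark for the sign test and the
#' analytic replication-power checks.
#'
#' @return data.frame with columns `phenotype`, `discovery_cohort`, `snp`,
#'   `disc_p`, `disc_af`, `disc_beta`, `disc_se`, `rep_p`, `rep_af`,
#'   `rep_beta`, `rep_se`.
#' @export
ail_benchmark_loci <- function() {
  path <- system.file("extdata", "ail_replication_loci.tsv",
                      package = "ailrep", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

tsv_write <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

#' Dosage TSV round trip
#'
#' Rows are SNPs: `snp_id`, `chrom`, `pos`, `cm`, optional `dosage_r2`,
#' then one dosage column per sample. Tab-delimited, "NA" for missing,
#' header mandatory.
#'
#' @param geno A `genotype_matrix`.
#' @param path File path.
#' @return `read_dosage_tsv` returns a `genotype_matrix`.
#' @export
write_dosage_tsv <- function(geno, path) {
  df <- data.frame(snp_id = geno$map$snp, chrom = geno$map$chrom,
                   pos = geno$map$pos, cm = geno$map$cm,
                   stringsAsFactors = FALSE)
  if (!is.null(geno$dosage_r2)) df$dosage_r2 <- geno$dosage_r2
  tsv_write(cbind(df, as.data.frame(geno$dosage)), path)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  meta <- intersect(c("snp_id", "chrom", "pos", "cm", "dosage_r2"),
                    names(df))
  samples <- setdiff(names(df), meta)
  map <- genetic_map(chrom = df$chrom, pos = df$pos,
                     cm = if ("cm" %in% meta) df$cm else NA_real_,
                     snp = df$snp_id)
  # genetic_map sorts by (chrom, pos); realign dosages
  ord <- match(map$snp, df$snp_id)
  genotype_matrix(as.matrix(df[ord, samples, drop = FALSE]), map = map,
                  samples = samples,
                  dosage_r2 = if ("dosage_r2" %in% meta)
                    df$dosage_r2[ord] else NULL)
}

#' Pedigree TSV round trip
#'
#' Columns `individual_id`, `sire_id`, `dam_id`, `sex`, `generation`; "0"
#' encodes a missing parent (founders).
#'
#' @param ped An `ail_pedigree`.
#' @param path File path.
#' @export
write_pedigree_tsv <- function(ped, path) {
  out <- as.data.frame(ped)
  out$sire_id[is.na(out$sire_id)] <- "0"
  out$dam_id[is.na(out$dam_id)] <- "0"
  tsv_write(out, path)
  invisible(path)
}

#' @rdname write_pedigree_tsv
#' @export
read_pedigree_tsv <- function(path) {
  ped <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(individual_id = "character",
                                          sire_id = "character",
                                          dam_id = "character"))
  ped$sire_id[ped$sire_id == "0"] <- NA_character_
  ped$dam_id[ped$dam_id == "0"] <- NA_character_
  ped$generation <- as.integer(ped$generation)
  class(ped) <- c("ail_pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

#' Phenotype TSV round trip
#'
#' First column `individual_id`, one column per trait, "NA" for missing.
#'
#' @param pheno data.frame with an `individual_id` column.
#' @param path File path.
#' @export
write_phenotype_tsv <- function(pheno, path) {
  stopifnot("individual_id" %in% names(pheno))
  tsv_write(pheno, path)
  invisible(path)
}

#' @rdname write_phenotype_tsv
#' @export
read_phenotype_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(individual_id = "character"))
}

#' Association table TSV round trip
#'
#' GEMMA-like columns: `chr`, `rs`, `ps`, `n_obs`, `af`, `beta`, `se`,
#' `p_wald`, `neg_log10_p`.
#'
#' @param assoc An `assoc_table`.
#' @param path File path.
#' @export
write_assoc_tsv <- function(assoc, path) {
  tsv_write(data.frame(chr = assoc$chrom, rs = assoc$snp, ps = assoc$pos,
                       n_obs = assoc$n, af = assoc$af, beta = assoc$beta,
                       se = assoc$se, p_wald = assoc$p,
                       neg_log10_p = assoc$neg_log10_p,
                       stringsAsFactors = FALSE), path)
  invisible(path)
}

#' @rdname write_assoc_tsv
#' @export
read_assoc_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chr = "character"))
  out <- data.frame(chrom = df$chr, snp = df$rs, pos = df$ps, n = df$n_obs,
                    af = df$af, beta = df$beta, se = df$se, p = df$p_wald,
                    neg_log10_p = df$neg_log10_p, stringsAsFactors = FALSE)
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' PLINK-1 text round trip
#'
#' Writes `<prefix>.ped` / `<prefix>.map` with allele labels from the map
#' (`a1`/`a2`); dosages are rounded to hard calls, missing becomes "0 0".
#' The .map genetic-distance column carries the cM position.
#'
#' @param geno A `genotype_matrix`.
#' @param prefix Path prefix (without extension).
#' @param sex,phenotype Optional per-sample columns for the .ped file.
#' @export
write_plink <- function(geno, prefix, sex = NULL, phenotype = NULL) {
  map <- data.frame(geno$map$chrom, geno$map$snp, geno$map$cm,
                    geno$map$pos)
  utils::write.table(map, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  hard <- round(geno$dosage)
  n <- length(geno$samples)
  a1 <- geno$map$a1; a2 <- geno$map$a2
  geno_str <- vapply(seq_len(n), function(j) {
    d <- hard[, j]
    al1 <- ifelse(is.na(d), "0", ifelse(d >= 1, a2, a1))
    al2 <- ifelse(is.na(d), "0", ifelse(d == 2, a2, a1))
    paste(rbind(al1, al2), collapse = "\t")
  }, character(1))
  sex_code <- if (is.null(sex)) rep(0L, n) else
    ifelse(sex == "male", 1L, 2L)
  ped <- paste("FAM", geno$samples, "0", "0", sex_code,
               if (is.null(phenotype)) rep(-9, n) else phenotype,
               geno_str, sep = "\t")
  writeLines(ped, paste0(prefix, ".ped"))
  invisible(prefix)
}

#' @rdname write_plink
#' @param prefix Path prefix.
#' @param a1,a2 Allele labels assumed when decoding dosages (defaults "A",
#'   "B", the writer's convention).
#' @export
read_plink <- function(prefix, a1 = "A", a2 = "B") {
  map_df <- utils::read.delim(paste0(prefix, ".map"), header = FALSE,
                              stringsAsFactors = FALSE,
                              colClasses = c(V1 = "character"))
  names(map_df) <- c("chrom", "snp", "cm", "pos")
  lines <- strsplit(readLines(paste0(prefix, ".ped")), "\t")
  m <- nrow(map_df)
  samples <- vapply(lines, `[[`, character(1), 2)
  dosage <- vapply(lines, function(f) {
    al <- matrix(f[-(1:6)], nrow = 2)
    d <- colSums(al == a2)
    d[al[1, ] == "0" | al[2, ] == "0"] <- NA_real_
    d
  }, numeric(m))
  dosage <- matrix(dosage, nrow = m)
  map <- genetic_map(chrom = map_df$chrom, pos = map_df$pos,
                     cm = map_df$cm, snp = map_df$snp, a1 = a1, a2 = a2)
  ord <- match(map$snp, map_df$snp)
  genotype_matrix(dosage[ord, , drop = FALSE], map = map, samples = samples)
}
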