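#' Default pipeline configuration
#'
#' Stage parameter blocks with the published analysis defaults (MAF 0.1,
#' HWE 1e-6, dosage r^2 0.9, heterozygosity 3 SD, clump r^2 0.1 / window
#' 12,150 kb, credible set r^2 0.8 / coverage 0.99, 1,000 permutations at
#' the 0.95 quantile, power grid 50 x 2,500, Bonferroni alpha 0.05). The
#' simulation block is desk-scale: a 10-generation pedigree standing in for
#' the deep AIL, with cohort sizes echoing the published 428/600 split via
#' `n1`/`n2` (scaled down by default so the demo runs in seconds).
#'
#' @param seed Global seed.
#' @param demo Use the fast demo scaling (default `TRUE`).
#' @return Nested list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1L, demo = TRUE) {
  cfg <- list(
    spec_version = "1.0",
    seed = as.integer(seed),
    sim = list(
      n_families = if (demo) 40 else 100,
      n_generations = 10, offspring_per_pair = 4,
      n_chrom = if (demo) 2 else 10,
      snps_per_chrom = if (demo) 60 else 200,
      chrom_length_bp = 1e8, cm_per_mb = 0.56,
      cohort1_generation = 8, cohort2_generation = 10,
      n1 = if (demo) 140 else 428, n2 = if (demo) 160 else 600,
      n_causal = 1, beta = 0.8, sigma_g2 = 0.3, sigma_e2 = 0.7,
      study_effect_sd = 0.3),
    qc = list(maf_min = 0.1, hwe_min = 1e-6, r2_min = 0.9, het_sd = 3,
              kinship_delta = 0.10),
    gwas = list(loco = TRUE, disc_threshold = 3),
    perm = list(n_perm = if (demo) 200 else 1000, quantile = 0.95),
    clump = list(r2 = 0.1, window_kb = 12150),
    credset = list(r2_min = 0.8, coverage = 0.99),
    replication = list(rep_alpha = 0.05),
    power = list(n_grid = if (demo) 5 else 50,
                 n_reps = if (demo) 100 else 2500,
                 max_effect = 0.5))
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks every stage block against its module's preconditions before any
#' stage runs; the first violation raises a validation error.
#'
#' @param cfg A `pipeline_config` (or plain nested list).
#' @return `cfg`, invisibly.
#' @export
validate_pipeline_config <- function(cfg) {
  num <- function(x, name, lo = -Inf, hi = Inf) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi) {
      stop("config validation: ", name, " must be a number in [",
           lo, ", ", hi, "]", call. = FALSE)
    }
  }
  num(cfg$seed, "seed")
  num(cfg$sim$n_families, "sim.n_families", 2)
  num(cfg$sim$n_generations, "sim.n_generations", 2)
  num(cfg$sim$offspring_per_pair, "sim.offspring_per_pair", 1)
  num(cfg$sim$cohort1_generation, "sim.cohort1_generation", 2,
      cfg$sim$n_generations)
  num(cfg$sim$cohort2_generation, "sim.cohort2_generation", 2,
      cfg$sim$n_generations)
  num(cfg$qc$maf_min, "qc.maf_min", 0, 0.5)
  num(cfg$qc$hwe_min, "qc.hwe_min", 0, 1)
  num(cfg$qc$r2_min, "qc.r2_min", 0, 1)
  num(cfg$qc$het_sd, "qc.het_sd", 0)
  num(cfg$perm$n_perm, "perm.n_perm", 100)
  num(cfg$perm$quantile, "perm.quantile", 0, 1)
  num(cfg$clump$r2, "clump.r2", 0, 1)
  num(cfg$clump$window_kb, "clump.window_kb", 0)
  num(cfg$credset$r2_min, "credset.r2_min", 0, 1)
  num(cfg$credset$coverage, "credset.coverage", 0, 1)
  num(cfg$replication$rep_alpha, "replication.rep_alpha", 0, 1)
  num(cfg$power$n_reps, "power.n_reps", 1)
  invisible(cfg)
}

#' Read / write a pipeline configuration (JSON)
#'
#' @param path File path.
#' @param cfg A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(cfg) <- c("pipeline_config", "list")
  validate_pipeline_config(cfg)
  cfg
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run the full two-cohort pipeline
#'
#' Executes simulate -> qc -> gwas (both cohorts) -> permutation threshold
#' -> clump / credible set -> replication (WC and WC+C) -> power -> mega in
#' dependency order, writing per-stage TSV/JSON outputs plus a manifest
#' (parameters, seeds, output checksums) under `out_dir`. A stage failure
#' halts with the stage name; prior outputs are left intact.
#'
#' @param cfg A `pipeline_config`.
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(cfg = default_pipeline_config(), out_dir) {
  validate_pipeline_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(spec_version = cfg$spec_version, seed = cfg$seed,
                   config = unclass(cfg), outputs = list())
  emit <- function(stage, file) {
    manifest$outputs[[stage]] <<- c(manifest$outputs[[stage]], file)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  sc <- cfg$sim

  # --- simulate -------------------------------------------------------
  stage("simulate", {
    map <- simulate_genetic_map(sc$n_chrom, sc$snps_per_chrom,
                                sc$chrom_length_bp, sc$cm_per_mb)
    ped <- build_ail_pedigree(sc$n_families, sc$n_generations,
                              sc$offspring_per_pair, seed = cfg$seed)
    geno_all <- gene_drop(ped, map, seed = cfg$seed + 1L)
    kin <- kinship_from_pedigree(ped)
    pick <- function(gen, n, seed) {
      ids <- ped$individual_id[ped$generation == gen]
      local_rng(seed)
      sample(ids, min(n, length(ids)))
    }
    ids1 <- pick(sc$cohort1_generation, sc$n1, cfg$seed + 2L)
    ids2 <- pick(sc$cohort2_generation, sc$n2, cfg$seed + 3L)
    g1 <- subset_genotypes(geno_all, samples = ids1)
    g2 <- subset_genotypes(geno_all, samples = ids2)
    af <- allele_freq(geno_all)
    common <- which(pmin(af, 1 - af) > 0.2)
    local_rng(cfg$seed + 4L)
    causal <- map$snp[sample(common, sc$n_causal)]
    tyr <- map$snp[common[which.max(common)]]
    agouti <- map$snp[common[1]]
    mk_spec <- function(seed) trait_sim_spec(
      "quantitative", causal_snps = causal,
      beta = rep(sc$beta, sc$n_causal), sigma_g2 = sc$sigma_g2,
      sigma_e2 = sc$sigma_e2, study_effect_sd = sc$study_effect_sd,
      seed = seed)
    ph <- function(g, ids, seed) {
      qt <- simulate_phenotypes(g, 2 * kin[ids, ids], mk_spec(seed))
      alb <- simulate_phenotypes(g, NULL,
                                 trait_sim_spec("albino"), tyr_proxy = tyr)
      ago <- simulate_phenotypes(g, NULL, trait_sim_spec("agouti"),
                                 tyr_proxy = tyr, agouti_proxy = agouti)
      data.frame(individual_id = ids, trait = qt$value,
                 albino = alb$value, agouti = ago$value,
                 stringsAsFactors = FALSE)
    }
    p1 <- ph(g1, ids1, cfg$seed + 5L)
    p2 <- ph(g2, ids2, cfg$seed + 6L)
    write_pedigree_tsv(ped, file.path(out_dir, "pedigree.tsv"))
    write_dosage_tsv(g1, file.path(out_dir, "cohort1_geno.tsv"))
    write_dosage_tsv(g2, file.path(out_dir, "cohort2_geno.tsv"))
    write_phenotype_tsv(p1, file.path(out_dir, "cohort1_pheno.tsv"))
    write_phenotype_tsv(p2, file.path(out_dir, "cohort2_pheno.tsv"))
    emit("simulate", c("pedigree.tsv", "cohort1_geno.tsv",
                       "cohort2_geno.tsv", "cohort1_pheno.tsv",
                       "cohort2_pheno.tsv"))
    sim <- list(g1 = g1, g2 = g2, p1 = p1, p2 = p2, kin = kin,
                causal = causal)
    sim
  }) -> sim

  # --- qc -------------------------------------------------------------
  stage("qc", {
    for (i in 1:2) {
      g <- sim[[paste0("g", i)]]
      snp_rep <- snp_filter(g, cfg$qc$maf_min, cfg$qc$hwe_min,
                            cfg$qc$r2_min)
      samp_rep <- sample_qc(g, k_sd = cfg$qc$het_sd)
      tsv_write(snp_rep, file.path(out_dir,
                                   sprintf("cohort%d_snp_qc.tsv", i)))
      tsv_write(samp_rep, file.path(out_dir,
                                    sprintf("cohort%d_sample_qc.tsv", i)))
      g <- subset_genotypes(g, snps = which(snp_rep$kept),
                            samples = which(samp_rep$kept))
      sim[[paste0("g", i)]] <- g
      pheno <- sim[[paste0("p", i)]]
      sim[[paste0("p", i)]] <-
        pheno[pheno$individual_id %in% g$samples, , drop = FALSE]
      emit("qc", sprintf(c("cohort%d_snp_qc.tsv",
                           "cohort%d_sample_qc.tsv"), i))
    }
    sim
  }) -> sim

  # --- gwas -----------------------------------------------------------
  scans <- stage("gwas", {
    out <- list()
    for (i in 1:2) {
      g <- sim[[paste0("g", i)]]
      y <- quantile_normalize(sim[[paste0("p", i)]]$trait)
      out[[i]] <- assoc_scan(y, NULL, g, loco = cfg$gwas$loco)
      write_assoc_tsv(out[[i]], file.path(out_dir,
                                          sprintf("cohort%d_assoc.tsv", i)))
      emit("gwas", sprintf("cohort%d_assoc.tsv", i))
    }
    out
  })

  # --- permutation threshold -----------------------------------------
  thr <- stage("perm_threshold", {
    y <- quantile_normalize(sim$p1$trait)
    K <- compute_grm(sim$g1)
    pt <- permutation_threshold(y, NULL, sim$g1, K = K,
                                n_perm = cfg$perm$n_perm,
                                quantile_ = cfg$perm$quantile,
                                seed = cfg$seed + 10L)
    jsonlite::write_json(list(threshold = pt$threshold),
                         file.path(out_dir, "perm_threshold.json"),
                         auto_unbox = TRUE)
    emit("perm_threshold", "perm_threshold.json")
    pt$threshold
  })

  # --- clump + credible set ------------------------------------------
  leads <- stage("clump", {
    cl <- clump(scans[[1]], sim$g1,
                p_threshold = 10^(-cfg$gwas$disc_threshold),
                r2 = cfg$clump$r2, window_kb = cfg$clump$window_kb)
    tsv_write(cl, file.path(out_dir, "cohort1_clumps.tsv"))
    emit("clump", "cohort1_clumps.tsv")
    cl
  })
  stage("credset", {
    if (nrow(leads)) {
      lead <- leads$lead_snp[1]
      ch <- leads$chrom[1]
      reg <- scans[[1]][scans[[1]]$chrom == ch & !scans[[1]]$monomorphic, ]
      z <- stats::setNames(z_from_assoc(reg$beta, reg$se, reg$p), reg$snp)
      cs <- credible_set(z, sim$g1, lead, r2_min = cfg$credset$r2_min,
                         coverage = cfg$credset$coverage)
      tsv_write(cs, file.path(out_dir, "cohort1_credset.tsv"))
      emit("credset", "cohort1_credset.tsv")
    }
    NULL
  })

  # --- replication ----------------------------------------------------
  stage("replicate", {
    res <- assess_replication(scans[[1]], scans[[2]],
                              disc_threshold = cfg$gwas$disc_threshold,
                              rep_alpha = cfg$replication$rep_alpha)
    jsonlite::write_json(
      list(M = res$M, t_disc = res$t_disc,
           empirical_rate = res$empirical_rate,
           wc = res$wc[c("model", "sigma_g2", "sigma_c1_2", "sigma_c2_2",
                         "loglik", "n_variants")],
           wcc = res$wcc[c("model", "sigma_g2", "sigma_c1_2", "sigma_c2_2",
                           "loglik", "n_variants")],
           predicted_rate_wc = res$predicted_rate_wc,
           predicted_rate_wcc = res$predicted_rate_wcc),
      file.path(out_dir, "replication.json"), auto_unbox = TRUE,
      digits = NA)
    emit("replicate", "replication.json")
    NULL
  })

  # --- power ----------------------------------------------------------
  stage("power", {
    snp <- if (nrow(leads)) leads$lead_snp[1] else sim$causal[1]
    x <- sim$g2$dosage[match(snp, sim$g2$map$snp), ]
    K2 <- compute_grm(sim$g2)
    y2 <- quantile_normalize(sim$p2$trait)
    nf <- fit_null(y2, NULL, K2)
    pc <- power_config(
      effect_sizes = seq(0, cfg$power$max_effect,
                         length.out = cfg$power$n_grid),
      n_reps = cfg$power$n_reps, gw_threshold = thr,
      seed = cfg$seed + 20L)
    pw <- replication_power(x, K2, nf, pc)
    tsv_write(pw, file.path(out_dir, "power_curve.tsv"))
    emit("power", "power_curve.tsv")
    NULL
  })

  # --- mega -----------------------------------------------------------
  stage("mega", {
    mega <- mega_scan(list(list(y = sim$p1$trait, geno = sim$g1),
                           list(y = sim$p2$trait, geno = sim$g2)),
                      loco = cfg$gwas$loco)
    write_assoc_tsv(mega, file.path(out_dir, "mega_assoc.tsv"))
    emit("mega", "mega_assoc.tsv")
    NULL
  })

  files <- unlist(manifest$outputs, use.names = FALSE)
  manifest$checksums <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
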