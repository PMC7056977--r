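Package: ailrep
Title: Two-Cohort GWAS Replication Analysis for Advanced Intercross Lines
Version: 0.1.0
Authors@R: person("AIL", "Replication Maintainers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis toolkit for assessing replication of
    genome-wide association results between two cohorts of a two-founder
    advanced intercross line (AIL). Provides gene-dropping simulation of
    AIL genotypes down a multigenerational pedigree, sample- and SNP-level
    quality control, a linear mixed model association engine with
    leave-one-chromosome-out genetic relatedness matrices and permutation
    significance thresholds, LD-based clumping and credible-set
    fine-mapping, replication power simulation, and random-effects models
    for paired discovery/replication z-scores that separate Winner's Curse
    from study-specific heterogeneity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
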