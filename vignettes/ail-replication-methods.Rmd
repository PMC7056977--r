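---
title: "Methods: replication analysis in a two-cohort advanced intercross line"
author: "ailrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: replication analysis in a two-cohort advanced intercross line}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ailrep)
```

# Scope

`ailrep` models a specific experimental situation: two cohorts drawn from
different generations of a single two-founder advanced intercross line
(AIL), phenotyped for overlapping traits, each analyzed by a linear mixed
model (LMM) GWAS, with loci discovered in one cohort tested for replication
in the other. The package provides every layer of that analysis on
synthetic data — it does not ship or download any real genotypes. A small
published 12-locus benchmark table (discovery and replication p, allele
frequency, beta, se in both directions between an F34 and an F39–43 AIL
cohort) is included as `ail_benchmark_loci()` for the fixed-number checks.

# The synthetic world

## Pedigree and gene dropping

`build_ail_pedigree()` starts from two inbred founders (generation 0), one
F1 litter, and then a fixed number of breeding pairs per generation, paired
at random with full-sibling avoidance *when possible* (in the F2 every
animal is a full sibling, so the constraint is best-effort by design). The
real colony's mating scheme and litter sizes are not published; one litter
of four per pair is our fixed choice, and nothing downstream is sensitive
to it beyond the effective population size.

`gene_drop()` assigns the founders opposite homozygous genotypes at every
SNP — the defining feature of a two-strain cross — and transmits gametes
down the pedigree with crossovers drawn independently in each marker
interval under the Haldane map function `r = (1 − exp(−2d/100))/2` (no
interference; the convention of gene-dropping software). Consequences that
the test suite verifies: the F1 is uniformly heterozygous, F2 genotype
frequencies are 1:2:1, markers at zero genetic distance co-segregate
perfectly, allele frequencies drift around 0.5, and LD decays with genetic
distance.

The default map is uniform (0.56 cM/Mb, the mouse genome-wide average) with
evenly spaced SNPs. Real GBS maps are clumpier; where local density
matters (credible-set calibration, below) the tests construct dense local
maps explicitly.

## Phenotypes

Quantitative traits follow `y = Wα + Σxβ + u + ε` with
`u ~ MVN(0, σg²K)` and `ε ~ MVN(0, σe²I)`; `K` is whatever relatedness
matrix the caller supplies (twice the pedigree kinship, or a GRM). Defaults
`σg² = 0.3, σe² = 0.7` give a moderately heritable trait on a unit scale.
Coat colors are Mendelian functions of flagged proxy SNPs: albinism is
recessive for the strain-B allele at the Tyr proxy; agouti is dominant at
its proxy and coded `NA` for albino animals, reproducing the standard
coding (albino 1 = white, 0 = non-white; agouti 1 = tan, 0 = black,
NA = white) in which albinism epistatically masks agouti.

An optional `study_effect_sd` perturbs each causal effect with a
cohort-specific Gaussian shift — the individual-level analogue of the
summary-level heterogeneity the replication models estimate.

## Summary-statistic pairs

`simulate_summary_pair()` draws directly from the random-effects generative
model: per variant a shared effect `λ ~ N(0, σg²)`, study effects
`δ(i) ~ N(0, σci²)`, unit noise, and `s(i) = λ + δ(i) + e(i)`. With an
ascertainment threshold it uses rejection sampling, which is exact;
efficiency is irrelevant at desk scale. Unascertained moments
(`Var(s1) = σg² + σc1² + 1`, `Cov = σg²`) are checked against Monte-Carlo
at n = 100,000.

What the generator does *not* emulate: genotyping error, genotype
likelihood/imputation uncertainty (dosage r² is carried as a pass-through
QC score only), sex chromosomes' dosage compensation, selection during
breeding, and non-equilibrium founder haplotype structure. A green test
establishes internal consistency of the statistical machinery on this
idealized world, not fidelity to any particular real colony.

# Quality control

Four sample-level screens mirror standard AIL practice: autosomal
heterozygosity beyond 3 SD of the cohort mean; sex inferred from the X/Y
read ratio against user-supplied intervals (the shipped defaults,
196.84–214.3 for females and 2.13–2.18 for males, are published
GBS-derived 95% CIs and are meant as realistic placeholders, not
universal constants); pedigree-vs-GRM relatedness discordance (expected
relatedness is `2 × kinship`, compared with GRM off-diagonals; the
"obvious disagreement" of colony practice is unquantified, so the default
`delta_max = 0.10` is ours and configurable); and coat-color concordance at
markers flanking the albino locus, where a recorded albino must be
homozygous for the albino-linked haplotype.

SNP-level filters: MAF ≥ 0.1, Hardy–Weinberg chi-square p ≥ 1e−6 (1 df, no
continuity correction, allele frequency estimated from counts; monomorphic
SNPs get p = 1 by convention and are removed by the MAF filter anyway),
and dosage r² > 0.9 when a score is present. SNPs that pass but sit within
10× of the HWE threshold are flagged `hwe_near`, the automatable part of
the "dubious SNP" review; the visual LD inspection that completed that
review in practice is not reproducible in code.

# The association engine

`compute_grm()` defaults to the centered GRM (the GEMMA default); the
standardized variant (unit-variance SNPs, mean diagonal ≈ 1) is available
because the exact convention used upstream is not documented. Missing
dosages are mean-imputed per SNP for both GRM and scan.

`fit_null()` is EMMA-style REML: one symmetric eigendecomposition of `K`
reduces the profiled criterion to 1-D optimization over
`λ = σg²/σe²`, searched on log10 scale over [−5, 5] with endpoint checks.
Boundary fits return without error. When `K` is proportional to the
identity the ratio is unidentified (the profile is flat); the fit then
prefers the smallest `λ` within 1e−7 of the maximum so that `σe²` carries
the variance — without this, downstream code that reads `σe²` alone would
see an arbitrary split.

`assoc_scan()` fixes the variance components at the null fit of the
matching LOCO GRM and runs generalized least squares per SNP in the
whitened space (the EMMAX approximation; exact per-SNP REML would change
p-values negligibly at these effect sizes while multiplying cost). The
test statistic uses a per-SNP residual variance and a t(n − c − 1)
reference. We deliberately prefer this over a fixed-σ² Wald chi-square:
it reduces *exactly* to OLS when `K` is absent, which gives the test suite
an independent oracle (`lm()` on whitened data), and it is what GEMMA's
Wald test does. Monomorphic SNPs are emitted with `beta = 0, p = 1` and a
flag rather than dropped, so row alignment with the input map survives.

Continuous traits are rank-inverse-normal transformed
(`Φ⁻¹((rank − 0.5)/n)`, ties averaged, missing preserved) before scanning;
binary coat traits are passed through untransformed and scanned with the
same LMM — a linear model on a binary outcome, which is how such data are
analyzed in this setting, with the usual caveat that effect sizes are on
the penetrance scale.

`permutation_threshold()` implements naive permutation: shuffle `y` against
the fixed (W, X), re-fit fixed effects every time, record the genome-wide
maximum −log10 p, and take the 95th percentile. Variance components are
held at the unpermuted null fit — permutation destroys the polygenic
structure, so at null the re-fit would simply find λ ≈ 0; holding the fit
is the standard shortcut and is validated in the tests against the Šidák
closed form `−log10(1 − 0.95^(1/m))` on independent SNPs.

`mega_scan()` pools individual-level data: per-cohort INT (binary traits
untouched), concatenated samples, a cohort indicator appended to the
covariates, scan on the SNP intersection.

# Loci

Clumping is the standard greedy procedure (most significant unassigned SNP
leads; significant SNPs within ± window and r² ≥ threshold join; repeat)
with defaults r² = 0.1 and a ±12,150 kb window. Ties on p break by
ascending position then id, for determinism. Credible sets restrict the
region to SNPs with r² ≥ 0.8 with the lead, assign posteriors
`∝ exp(z²/2)` (equal-prior Bayes-factor approximation, log-sum-exp
stabilized), and return the smallest descending-posterior prefix reaching
0.99. The exact Bayes factor inside the script this follows is not
published; `method = "wakefield"` (approximate Bayes factor, prior effect
variance 0.04) is offered as the principled alternative. The
`conditional_scan()` appends conditioning-SNP dosages to the covariates and
rescans, dropping collinear conditioners with a warning — a deliberate,
transparent simplification of stepwise model selection.

A calibration note: coverage of the 0.99 credible set depends on the map.
On a dense local map (tens of SNPs over a few cM, GBS-like) the causal SNP
is covered in ≥ 90% of simulations; on sparse maps the r² ≥ 0.8 region
filter itself can exclude the causal SNP when a neighbour happens to lead.
That is a property of the published procedure, not of this implementation,
and the tests state the dense world explicitly.

# Replication

The empirical replication rate is the fraction of the M
discovery-significant variants with two-sided replication p below 0.05/M.
Sign consistency is *not* required by default (the Bonferroni definition
mentions only a threshold); a sign-consistent option exists because the
lead-locus benchmark adds "same sign". `sign_test()` counts strict sign
agreement — a zero beta counts as disagreement, the conservative and
deterministic choice.

`fit_replication_model()` maximizes, over the variance parameters, the
product over variants of the truncated marginal of `s(1)` (normalizer
`2Φ(−t/√v1)`) times the conditional of `s(2)` given `s(1)`. Replication
statistics are not treated as ascertained. Whether the framework this
follows integrates the ascertainment region jointly over both statistics
is not published; the factorization above is our declared choice and its
consequences are measured (below). WC (one parameter) is fitted by Brent
on the log-variance scale; WC+C uses L-BFGS-B multi-start (moment-based
plus spread starts, bounds `log σ² ∈ [−12, 12]`), and additionally
evaluates the WC optimum embedded at exactly `σc² = 0`, so the nesting
inequality `loglik(WC+C) ≥ loglik(WC)` holds exactly rather than up to the
boundary approximation.

Two measured properties are worth stating honestly. First, the
ascertainment term matters: fitting the untruncated likelihood to
ascertained data inflates `σg²` by ~15–40% in our simulations (the
Winner's Curse itself); the truncated MLE is unbiased within Monte-Carlo
error. Second, under this factorized likelihood the WC model's `σg²` is
disciplined by the replication marginal, so on heterogeneity-dominated
synthetic data the WC-predicted rate is grossly optimistic (5–10× the
empirical rate) but not literally 1.000; predicted rates of exactly 1
arise when discovery z-scores are enormous (as with Mendelian coat-color
loci). The package's diagnostic contrast — WC wildly overpredicts, WC+C
tracks the empirical rate within a few points — is robust across every
parameterization we simulate.

# Power

`replication_power()` re-creates traits from the null-model fit of the
replication cohort (intercept + polygenic + residual, variance components
from REML) with the tested effect injected on the normalized-trait scale,
and scans the test SNP with the same GLS used in the GWAS. The published
design is 50 effect sizes × 2,500 scans; the defaults keep those numbers
and the tests scale down honestly (grid and reps are configuration, not
behavior). `analytic_power()` — `P(|N(β/se, 1)| > z)` — is the closed-form
companion; simulation and analytic agree within Monte-Carlo error when no
kinship structure is present. Covariates in power simulations reduce to an
intercept; a full-covariate simulation would only be meaningful with a
specific covariate model in hand.

# Pipeline and formats

`run_pipeline()` executes simulate → QC → GWAS ×2 → permutation threshold
→ clump/credible set → replication (both models) → power → mega-analysis,
writing TSVs, JSON, and a manifest with md5 checksums; identical config +
seed gives byte-identical outputs, which the tests assert. The config is
JSON with a `spec_version` field; every stage block is validated against
its module's preconditions before anything runs. All tabular IO is
tab-delimited with `NA` sentinels and mandatory headers; chromosome names
accept `chr` prefixes and are normalized to bare strings. The pipeline's
demo scaling (10-generation pedigree, two chromosomes, ~100 mice per
cohort) exists to keep the end-to-end run in seconds; the published
cohort sizes (428/600) are the non-demo defaults.

# Known limitations

- The LMM treats the X chromosome like any autosome; no dosage
  compensation model.
- Binary traits use the linear mixed model, not a liability model.
- The WC/WC+C framework assumes additive effects; a dominant Mendelian
  trait (agouti) violates this, and no dominance extension is attempted.
- Heterogeneity is estimated, never attributed: the models say *that*
  study-specific variance exists, not what caused it.
- The conditional rescan is a single-step conditioning, not stepwise model
  selection; multivariate-normal analytical thresholds are not
  implemented (permutation is the supported route).
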