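---
title: "MethylCascade: models, assumptions and design choices"
author: "MethylCascade authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MethylCascade: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: what each stage
assumes, which knobs matter, what the synthetic-data generator does and does
not emulate, and the choices we made where the design was genuinely open.
Every empirical statement here is one the test suite or
`scripts/acceptance.R` computes; nothing is quoted from elsewhere.

# The discovery cascade

The pipeline integrates three layers of evidence about TET2-regulated
genes:

1. **Knockout evidence.** Methyl-capture sequencing and RNA-seq of
   TET2-knockout versus parental prostate cells, in duplicate, with an
   unenriched input control. A gene is knockout-responsive if it loses
   expression (p < α, fold change < 0.75) in *either* knockout line and
   gains promoter methylation (p < α) in either line. "Either" is a
   deliberate OR: two independent knockout clones are two chances to
   observe the same biology, and the overlap statistic is reported
   separately.
2. **Cohort concordance.** Tumors in the bottom decile of TET2 expression
   (the *low-anchor subset*) stand in for the knockout condition in
   patients. Each knockout-down gene is tested (two-sided Mann-Whitney,
   low-anchor tumors vs normals) against the Bonferroni threshold
   α divided by the *size of the knockout-down family* — the family the
   selection actually screens. A direction gate requires the tumor ranks
   to be lower; a two-sided p alone would admit genes moving the wrong
   way.
3. **Clinical utility.** The surviving panel is scored for association
   with recurrence, stage and Gleason grade (rank tests), tumor/normal
   classification (ROC, logistic regression on expression and on
   M-values), and recurrence-free survival (outcome-optimized cutpoints
   with a validation split).

The panel object records, per gene, a flag per tier plus provenance (DMR
coordinates, mapped probe ids); the *tier* is the number of consecutive
cascade stages passed, so tier counts are monotone non-increasing along
the funnel by construction.

# Stage models and assumptions

## Peak calling and differential methylation

`callPeaks()` is a deliberately transparent enrichment caller for windowed
counts: per fixed-width window the treatment count is referred to a
Poisson upper tail with expectation
`max(depth-scaled input count, global background rate) + 0.5`. The
pseudo-count of 0.5 keeps zero-input windows from producing zero-rate
tails; the global background floor protects against under-covered input
regions. Significant windows merge across at most `mergeGapWindows`
non-significant windows (default 1). This trades the fragment-shift and
local-λ machinery of full peak callers for auditability — the cascade
logic, not the caller, is the scientific content, and the default 200 bp
window approximates fragment-scale resolution.

Consensus regions are the union of per-sample peaks ("peak in at least one
sample"), and differential methylation re-uses the count test below on
region-summed counts, with library-size normalization (capture depth, not
composition, dominates region counts). Direction is `gain` when the
normalized knockout mean exceeds the parental mean; swapping condition
labels flips every direction and preserves p-values (tested).

## The two-group count test

`nbExactTest()` assumes counts are negative binomial with variance
μ + φμ², a *common* dispersion φ across genes: with two replicates per
condition there is no information for per-gene dispersion, and the
cascade consumes only the p < α decision. Size factors are median-of-ratios
(well-defined on synthetic data; a divergence from TMM-style normalization,
recorded here). φ is estimated by pooled method of moments — the pooled
within-condition variance against the pooled mean, floored at zero *after*
pooling; flooring per gene first would bias φ̂ upward at n = 2. The test
conditions on the total of the normalized group sums: group sums are
NB(nμ, n/φ), and the two-sided p sums the conditional probabilities not
exceeding that of the observed split (no small-p doubling). At φ = 0 the
conditional law is binomial, which is the oracle the tests enumerate.

## Genomic annotation

Promoters are −1500 bp to +500 bp around the TSS in the direction of
transcription, clipped at zero; on the minus strand the TSS is the last
base of the span (standard BED/GTF conversion). Region classification has
precedence promoter > gene body > intergenic, with overlap ties broken by
nearest TSS and intergenic assignment capped at 100 kb (the annotation
tools this mirrors have unstated tie-breaks; ours are deterministic and
recorded in output provenance). Probe-to-DMR proximity is inclusive: a
probe inside a region has gap 0, and a probe whose strictly-between
distance to the nearest edge is ≤ 500 bp is assigned.

## Rank statistics

Exact null distributions are used only where enumeration is honest: the
Mann-Whitney and signed-rank tests switch to exact mode at combined
n ≤ 12 with no ties, else the normal approximation with tie and
continuity corrections (cohort-sized comparisons always take the
approximation, matching practice at n in the hundreds). The Dunn post hoc
uses the joint-ranking z statistic with the usual tie term, Bonferroni
over the pairs, capped at 1; it is reported only under a significant
Kruskal-Wallis omnibus. Stage is a user-supplied binary grouping (the
dichotomy is not standardized; we expose it as a column rather than guess).
Matched tumor/normal expression is compared *unpaired*, mirroring how the
corresponding association tables are computed; Gleason 3+4 and 4+3 are
distinct groups (GS7a/GS7b) in the methylation scheme and pooled (GS7) in
the expression scheme.

## Classification

AUC uses the rank formulation with half credit for ties; its variance is
DeLong's placement variance, and the 95% CI is truncated to [0, 1]. The
optimal cutoff maximizes Youden's J over midpoints of adjacent distinct
scores — the standard reading of "maximizing both values" — with ties
broken toward higher specificity, then the lower cutoff; the marker
direction is auto-detected from the AUC side, and reported AUCs are
orientation-corrected (a marker *lost* in tumors classifies by low
values). Beta values enter logistic models as M-values,
log2(β/(1−β)) with ε = 10⁻⁶ clipping (the standard 450k convention;
base 2 chosen explicitly since "M-value" does not pin the base).
Logistic fits are maximum likelihood via IRLS with Wald p-values and
exp-scale CIs; non-convergence and separation are flagged, never silently
returned. The multivariate model is all panel members jointly with an
intercept and no interactions; clinical covariates can be appended but are
not included by default (whether the original multivariate models included
them is unstated, so the default is the panel-only model).

## Survival cutpoints

`xtileCutpoint()` splits the cohort 1:1 at random under a mandatory seed
(the original tool's split ratio is unpublished; 1:1 is recorded in the
result), scans every midpoint between adjacent distinct marker values that
leaves ≥ 10% of training samples on each side, picks the argmax log-rank
χ² (ties → lower cutpoint), and evaluates the log-rank p on the held-out
half. If the selected cutpoint empties a validation group, the next-best
training division is used. The log-rank statistic uses standard
hypergeometric accounting at tied event times and is implemented as a
vectorized scan primitive (`survival::survdiff` is the independent
cross-check in the tests, and the permutation law the oracle). The
whole-cohort optimized p (`trainFraction = 1`) is exposed deliberately so
its anti-conservatism can be demonstrated: over null markers the
validation p rejects near the nominal 5% while the optimized p rejects
several-fold more often (asserted in the acceptance suite over 200 seeds).

## MethyLight

ΔΔCt quantification averages replicates on the Ct scale (standard
practice), references ALU within sample and a supermethylated control
across samples, and reports 100·2^−ΔΔCt — percent of the fully methylated
reference. Values above 100% are possible and flagged, not truncated
(truncation would bias the paired test). QC excludes samples whose
replicate-mean ALU Ct *exceeds* 30 (30.0 is retained); the rule is applied
per-mean rather than per-replicate (the convention is unstated; per-mean is
the default and configurable). Pairs lost to QC reduce the effective n of
the paired signed-rank test and are logged — which is how a 19-pair plate
honestly becomes an n = 18 comparison.

# The synthetic-data generator

The generator is first-class code: it defines the study conditions the
package is validated under.

**Knockout arm.** Genes sit every 20 kb on four chromosomes; expression
counts are NB with log-normal baselines (log-mean log 150, log-sd 1),
per-sample library factors U(0.8, 1.2) and common dispersion φ. Planted
drivers have their knockout mean multiplied by `driverExprFc` (default
0.5) in both knockout lines. Methylation windows (200 bp, 20 per gene)
carry background Poisson noise (mean 5) plus a 3-window enrichment block
(mean 30 per window) at each TSS in the captured samples; driver blocks
are multiplied by `driverMethFc` (default 3) in knockouts. The input
sample sees background only.

**Dispersion default.** φ defaults to 0.01 (biological CV 0.1). The
knockout arm models *isogenic cell lines*, where replicate variability is
an order of magnitude below human-tissue RNA-seq; at tissue-scale
dispersion (φ = 0.1) the two-replicate design has a hard power ceiling
(per-line down-call power ≈ 0.5 by simulation) and no analysis could
recover most planted drivers — the data, not the method, would be the
limit. At φ = 0.01 the per-line power is ≈ 0.99, so the cascade's recovery
measures the pipeline rather than an under-powered design.

**Cohort arm.** Tumors carry a latent TET2 activity t ~ U(0, 1) (deficit
d = 1 − t); the reserved anchor gene "TET2" expresses proportionally to
0.2 + 0.8t. Driver expression in a tumor is multiplied by
`driverExprFc^(0.5 + d)`: a baseline tumor downregulation (half the
knockout log-fold change) amplified in proportion to the TET2 deficit.
This mirrors a cohort in which candidate loss marks tumors generally and
TET2-low tumors most strongly — the regime in which the candidates are
useful classifiers at all — rather than an effect confined to the bottom
decile. Probe betas are logit-normal (sd 0.5) around 0.2 in normals,
shifted in driver promoters by 0.25 + 0.75d of the full planted shift
(default to 0.6). Recurrence hazard is log-linear in the standardized mean
driver expression (hazard ratio default 3 per SD, baseline rate 0.15/yr);
follow-up is exponential with U(0, c_max) censoring, c_max solved so the
expected censored fraction matches `censorRate`. Gleason grade and a
binary stage group scale with the deficit. These effect sizes are
calibration choices made once from design-time power analysis, not
estimates from any dataset, and the null configurations (all effects at 1)
are what the type-I-error suite runs on.

**What it does not emulate.** Read-level artifacts (GC, mappability,
duplicates), copy-number and mutation structure, ERG-fusion subtypes,
batch effects, correlated genes, and probe cross-reactivity. Passing tests
therefore demonstrate the *statistical* correctness and the cascade's
operating characteristics under the stated generative model — not
robustness to the full messiness of real cohorts.

# Numerical conventions

- Coordinates: 0-based half-open (BED) at every file interface and in the
  documented examples; 1-based GRanges internally, converted in exactly
  one place (`bedToGRanges()`/`grangesToBed()`).
- Thresholds are inclusive where stated: CPM ≥ 1 in ≥ 2 samples; probe
  gap ≤ 500 bp; ALU Ct > 30 excludes (strict).
- Bonferroni thresholds are always derived from the actual number of tests
  run at that stage and recorded in the panel metadata (published
  per-test thresholds imply family sizes that are not always stated; we
  never hard-code one).
- Degenerate inputs error loudly: empty groups, all-zero paired
  differences, constant markers, perfect separation, missing anchor gene.
- All randomness flows through explicit seeds (`withr::with_seed`), with
  fixed offsets separating the knockout, cohort, prior-list and plate
  streams; every generator is byte-reproducible.

# Problem sizes in the test and acceptance suites

The suites run at desk scale, chosen to keep each property statistically
meaningful: 500 genes / 20 drivers / 200 tumors / 40 normals for the
full-cascade recovery run; 1000-2000 null genes or replicates for
calibration checks; 200 seeds for the cutpoint-optimism comparison;
exhaustive enumeration (≤ 252 arrangements) for the exact-test oracles.

# Known limitations

- The common-dispersion exact test is conservative at very low counts
  (its null p-values are uniform at consensus-region scale, not at
  single-window scale).
- The Poisson caller has no local background model; strong copy-number
  variation would confound it.
- The prior-evidence list is an input, not a computation — its quality
  bounds the corresponding tier.
- Cutpoint validation controls optimism but halves the data; with few
  events the validation log-rank is noisy.
- Matched tumor/normal comparisons are intentionally unpaired (mirroring
  the association-table convention), which forfeits pairing power.
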