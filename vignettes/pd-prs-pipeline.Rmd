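---
title: "Methods: the PD polygenic risk score pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the PD polygenic risk score pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdprs)
```

## The problem

Genome-wide association studies of Parkinson disease (PD) have produced a
set of replicated risk loci, each with a small per-allele odds ratio. A
polygenic risk score (PRS) aggregates them into one per-individual number
— the weighted sum of effect-allele dosages — and asks whether that
cumulative genetic load associates with disease status, with age at onset,
and with cerebrospinal fluid (CSF) biomarker levels measured on different
immunoassay platforms. This package implements that pipeline end to end:
panel construction from a published locus table, genotype quality control,
scoring, cross-platform biomarker harmonization, and the association
suite, plus a synthetic-data generator that stands in for the
access-controlled cohorts such studies are run on.

## Score construction

**Weights.** Each locus weight is the binary logarithm of its published
per-effect-allele odds ratio, `w = log2(OR)`, so protective alleles (OR <
1) get negative weights and OR = 1 carries no weight. The packaged
26-locus table also ships the published weight column; by default
(`use_printed_weights = TRUE`) a published weight takes precedence over
the recomputed one, because three of the published weights are not
`log2(OR)` of the published odds ratio (the SNCA, INPP5F and MAPT rows)
and fidelity to the published score matters more for reproduction than
fidelity to the stated rule. Both behaviours are exposed and tested.

**Panel selection.** A variant is scoreable only if its overall
(genotyped-or-imputed) call rate is strictly greater than the threshold
(default 0.85) and it has a defined weight. Two table rows have no
genotype data at all and are never selectable. With the packaged table the
rule yields a 16-variant panel. Ties at exactly the threshold are
excluded: the comparison is strict.

**The score.** `PRS_i = sum_j w_j d_ij` over panel variants, a plain
weighted sum of dosages in [0, 2], not a per-allele average. The sum keeps
leave-one-variant-out scores exactly additive (`full − dosage×weight =
reduced`, tested to 1e-12), which is what makes the sensitivity analyses
clean. A missing dosage is mean-imputed as `2 × study MAF` (the
Hardy-Weinberg expected dosage) or, by flag, omitted with
`n_variants_used` decremented. With all-heterozygous dosages the score
equals the sum of the 16 published weights, 1.287.

**Tertiles.** Samples are ranked by score with ties broken by sample ID
(bit-reproducible), and the ranking is cut at `ceiling(n/3)` and
`ceiling(2n/3)`; T1 holds the lowest scores.

## Genotype quality control

Thresholds (all configurable through `qc_thresholds()`):

| filter | default | acts on |
|---|---|---|
| hard-call minimum genotype probability | 0.9 | single genotypes |
| minimum imputation INFO | 0.3 | whole variants (masked) |
| Hardy-Weinberg exact-test alpha | 1e-6 | variants (dropped) |
| per-platform genotyping rate | 0.95 | variants (dropped) |
| joint post-merge call rate | 0.85 | variants (dropped) |

When genotype probability triples are absent (plain dosage files), the
hard-call clause masks genotypes whose dosage lies farther than 0.1 from
the nearest integer — the equivalent confidence requirement expressed on a
best-guess dosage. Filters only mask or remove; a surviving dosage is
never altered, and the full chain is idempotent. The per-platform 95% rule
is applied within each array/platform and the 85% rule on the merged
matrix, mirroring a per-platform imputation followed by joining. HWE is
computed on hard-called genotypes (dosages rounded to integers) over cases
and controls jointly; restricting to controls is left to the caller by
subsetting, since the merged-cohort convention is what the packaged
defaults emulate.

**The HWE exact test** is the conditional exact test on heterozygote
counts given allele counts: the p-value sums the probabilities of all
heterozygote counts no more probable than the observed one. The
distribution is evaluated with a multiplicative recurrence over the
support (heterozygote counts stepping by 2), with periodic rescaling, so
cohorts of thousands of samples do not overflow; the suite checks it
against a log-factorial enumeration oracle at small counts and against
1-df chi-square asymptotics at large counts. Deep in the tail (p ~ 1e-10)
the chi-square approximation drifts beyond 10% relative, so the deep-tail
comparison is made on the log scale.

**Ancestry restriction** computes principal components of the
mean-imputed, allele-frequency-standardized dosage matrix
(`(d − 2p)/sqrt(2p(1−p))`), then partitions samples on PC1–PC2 by 2-means
seeded deterministically at the two most distant samples. A plain 2-means
always produces two clusters, so the partition is accepted only when the
center separation exceeds twice the within-cluster RMS spread; otherwise
the sample is treated as one cluster and everyone is retained. The cluster
containing a declared reference set (majority vote) is kept, or the larger
cluster when none is declared. Zero-variance input is an error, not an
arbitrary split. PC1/PC2 feed the downstream models as admixture
covariates.

## Association models

All betas are per PRS unit; CIs are Wald at 95%; no multiple-testing
correction is applied anywhere (per-variant results are labelled nominal).

* **Status**: logistic regression `status ~ PRS + age at last assessment +
  sex + PC1 + PC2`, sex coded female = 1. "General linear model" for a
  binary trait is read as logistic: betas of ~5 per PRS unit are only
  interpretable on the log-odds scale. Complete separation is reported as
  a flagged, non-converged result (detected from glm warnings and from the
  estimate/standard-error signature) rather than as a crash; a constant
  score is an error.
* **ROC increment**: apparent AUC of the covariate-only model's fitted
  probabilities vs covariates + PRS (Mann-Whitney AUC via pROC, checked
  against a brute-force pairwise-concordance oracle). Apparent, not
  cross-validated: the increment is a descriptive quantity here.
* **Age at onset**: Cox proportional hazards with onset as the event and
  controls censored at last assessment, `~ PRS + sex + PC1 + PC2` (age is
  the time scale, so no age covariate), Efron tie handling. A positive
  hazard beta means higher score, earlier onset. The cases-only flag
  refits without controls to probe censoring artifacts.
* **Tertile analysis**: Kaplan-Meier product-limit curves per tertile, a
  T1-vs-T3 log-rank test, and the first-vs-third-tertile effect. No
  standard estimator turns a log-rank test into an odds ratio, so the
  effect is reported as the exponentiated Cox coefficient of a T3-vs-T1
  indicator fit on the outer tertiles with the same covariates, and is
  labelled hazard-ratio scale.
* **Biomarkers**: linear model of the harmonized level on
  `PRS + age at lumbar puncture + sex + PC1 + PC2`.
* **Stratified reruns** split the case population by family history and
  keep all controls in both strata; single-variant tests substitute each
  panel variant's dosage for the score and keep exactly one result row per
  panel variant, flagging monomorphic variants as degenerate.

## Biomarker harmonization

Raw CSF levels from different kits differ by large multiplicative factors
(e.g. amyloid-beta 1-42 control means of ~378 vs ~926 pg/mL on the two
emulated platforms) and cannot be pooled. Harmonization log10-transforms
the raw levels and centers each platform × analyte stratum at its mean.
Centering only — no division by the stratum SD — because the observed
combined-cohort dispersions (~0.12–0.21 on the log10 scale) are raw
log-scale dispersions, not unit variances; "standardize to zero" is
location, not scale. Centering makes the harmonized values exactly
invariant to per-platform rescaling (kit recalibration drops out,
assertable to 1e-12) and is idempotent. Strata deliberately pool cases and
controls: centering within status would erase the case-control contrast
the models test. Singleton strata and non-positive levels are errors.

## The synthetic generator

`simulate_cohort()` emulates the study conditions the analysis assumes,
so the whole pipeline is testable without restricted data. Defaults (set
once; all configurable through `simulation_config()`):

* two platforms with 336/139 and 493/293 cases/controls (1261 total);
* genotypes Binomial(2, study MAF) per panel variant — HWE by
  construction — with hard-call-consistent probability triples and
  per-variant missingness matching the published call rates;
* disease status from a logistic liability on the raw PRS with
  `effect_scale` 1.0 (per-allele odds ratios equal to the panel's), the
  intercept solved per platform by root-finding so the expected case
  fraction matches the configured counts;
* case onset age `61 − 4 × (PRS − mean PRS) + N(0, 9)` years, truncated
  to [25, 95]; control age at last assessment N(64, 9). Cases' age at
  last assessment — needed by the status model but unspecified beyond
  cohort means — is onset plus an exponential follow-up of mean 3 years;
* sex female fractions 0.3353 (cases) / 0.4560 (controls); family-history
  rates 0.25 / 0.03;
* biomarker log10 levels at per-platform kit locations (log10 of
  control-mean pg/mL), residual sd 0.15, with per-analyte PRS effects
  defaulting to zero (a null generator for the biomarker models).

Everything is deterministic given the seed (the three stages draw from
seed, seed+1, seed+2 so adding a stage never perturbs another). What the
generator does *not* emulate: linkage disequilibrium between panel loci
(treated as independent GWAS hits), genome-wide background variation,
platform batch effects beyond location shifts, age-dependent ascertainment,
and genuine effect-size heterogeneity between risk and onset (the same
weights drive both, scaled by one knob each). Passing tests therefore
demonstrate correctness of the statistical machinery under the stated
generative model, not performance on real cohorts — in particular the
printed real-data association betas are not reproducible from synthetic
data and are not targeted.

## Numerical choices and test scale

* HWE recurrence rescaled at 1e250 to avoid overflow; observed-probability
  comparison uses a 1+1e-7 slack, the convention for this test.
* Tertile ties broken by sample ID; k-means seeded at the two most distant
  samples; both make reruns bit-identical.
* Wald CIs throughout; Efron ties in Cox; logistic/linear fits are plain
  `glm`/`lm` with no penalization — separation is flagged, not resolved.
* Degenerate inputs error early with the offending sample/variant named:
  non-positive odds ratios, dosages outside [0, 2], probability triples
  summing above 1, all-censored survival input, empty tertiles, singleton
  harmonization strata, constant predictors.
* The test suite exercises parameter recovery at the default study size
  (n = 1261, 100 seeded replicates for direction and magnitude of the
  status and onset effects) and null calibration with an effect-free
  generator (n = 300, 200 replicates; every test's type-I error within
  the binomial 95% band around 0.05). These sizes were chosen as the
  smallest that make direction-recovery and calibration claims
  statistically meaningful.

## Known limitations

* Allele matching between panel and genotype file is by variant ID plus
  effect allele, with an error on mismatch — no strand flipping or
  liftover; chromosome/position are metadata.
* The printed theoretical score range of the original 16-variant panel
  (max 2.5, min −2.1) is not reproducible from the published weights
  under a plain dosage-weighted sum (2×Σ positive weights = 5.02,
  2×Σ negative = −2.45); the scaling convention behind those printed
  bounds is unstated, and this package makes no attempt to match them.
* Apparent (not cross-validated) AUCs; no LD-proxy search for the ten
  unusable loci; no genotype imputation, relatedness or sex-check QC —
  those belong upstream of this pipeline.
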