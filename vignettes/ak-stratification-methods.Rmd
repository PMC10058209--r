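---
title: "Methods: transcriptomic stratification of actinic keratoses"
author: "akstrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptomic stratification of actinic keratoses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(akstrat)
```

## The problem

Actinic keratoses (AKs) are sun-induced premalignant keratinocyte lesions.
A fraction of them progress to squamous cell carcinoma (SCC), but neither
clinical inspection nor histological grading (AK I–III) predicts which.
Transcriptome profiling suggests AKs are molecularly heterogeneous: some
resemble healthy skin, others resemble carcinoma. `akstrat` implements a
complete, testable pipeline that makes that observation operational:

1. build an SCC-vs-healthy expression signature from paired reference
   samples using two competing differential-expression (DEG) routes;
2. pick the better route by nearest-centroid classification accuracy on a
   held-out test group;
3. stratify AK samples into a healthy-like subclass (`AK_NL`) and a
   carcinoma-like subclass (`AK_L`) by their distance to the reference
   centroids in signature PCA space;
4. characterize the two subclasses (progression DEGs, signature overlap,
   clustering, marker trends, grade composition).

## Data model

The pipeline consumes a probes × samples matrix of log2 intensities and a
per-sample metadata table: `sample_id`, `patient_id`, `histology`
(`H`, `AK_I`–`AK_III`, `SCC`), `site_class` (`NL` non-lesional, `L`
lesional, `AK`) and `group_role` (`reference`, `test`, `ak`). Reference
patients must contribute at least one NL and one L sample so the paired
model is estimable.

## The two DEG routes

Both routes test lesional against non-lesional reference samples and apply
the same selection rule — p-value strictly below 0.05 and absolute
linear-scale fold change strictly above 2 (`|FC| > 2` ⇔ `|log2FC| > 1`;
a probe at exactly FC = 2 is excluded):

* **Paired route** (`paired_linear_model()`): quantile normalization
  between arrays (`quantile_normalize()`, the averaged-order-statistics
  method with tied ranks receiving the mean of their normalized values),
  then, per probe, an ordinary least-squares fit of expression on the
  diagnosis factor plus patient indicator variables, a two-sided t test on
  the diagnosis coefficient, and Benjamini–Hochberg adjustment. No
  empirical-Bayes variance moderation is applied: the statistic is the
  classical OLS t, which on a complete paired design reduces exactly to the
  paired t test (this equivalence is a unit test).
* **t-test route** (`two_group_ttest()`): additive shift of each array so
  its 75th percentile of log2 intensity equals zero
  (`percentile_shift_normalize()`, linear-interpolation percentiles), a
  pooled (equal-variance) two-sample t test per probe, and Bonferroni
  adjustment. The pooled-variance convention is deliberate; it is the
  classical default of array-suite t tests.

Raw linear-scale intensities can be prepared with `background_correct()`:
optional background subtraction floored at zero plus an offset (default
50), guaranteeing log-safe positive values.

Probes with zero residual variance get `t = 0`, `p = 1` rather than `NA`,
so downstream set operations stay total. Signatures can be collapsed from
probe to gene-symbol level with `collapse_to_symbols()`; when probes
sharing a symbol disagree on direction, the probe with the smallest
p-value represents the symbol and the conflict is reported — a
deterministic, conservative rule.

The fold-change threshold is interpreted on the linear scale for both
routes for comparability. Readers who prefer the stricter `|log2FC| ≥ 2`
reading can pass `abs_fc_threshold = 4` to `select_degs()`.

## Classification and pipeline selection

`fit_centroid_classifier()` performs PCA with the reference samples as
observations and the signature probes as variables. Probes are centered by
their reference means but not variance-scaled (the signature already
restricts to strongly changing probes; scaling would up-weight noisy
low-variance ones). The number of components retained for inspection is
the smallest k whose cumulative explained-variance ratio exceeds 0.75.
Distances, however, are measured in the plane of the first two components
— the space in which the reference centroids are defined — unless the
model is fitted with `distance_pcs = "retained"`. Each loading vector's
largest-magnitude coefficient is made positive so score signs are
reproducible across platforms.

A sample is labeled by the nearer centroid under Euclidean distance. An
exactly equidistant sample is assigned the NL-side label and flagged as a
tie: ties are measure-zero but the rule must be deterministic.

`evaluate_accuracy()` reports the exact fraction correct plus a rounded
whole percent (half away from zero); with a test group of 19, one error
gives 94.7 % ≈ 95 % and two give 89.5 % (reported as 89 % only under
round-half-down conventions — the package keeps the exact fraction
alongside the percent precisely because rounding conventions differ).
`select_pipeline()` compares the two routes' exact accuracies on the same
test set and returns the winner; an exact tie goes deterministically to
the t-test route, which carries fewer modeling assumptions.

`stratify_ak()` projects AK samples into the winning signature-PCA space
and labels each `AK_NL` or `AK_L`. Histological grades are joined into the
report for reading convenience but never influence the classification.
The published 21-sample validation table shipped with the package
(`published_ak_table()`) lets users confirm that the decision rule
reproduces the published subclass column from the printed distance pairs
alone (21/21, a 12/9 split, and a 44 % grade-I share among `AK_L`).

## Downstream characterization

* `hcluster()` — agglomerative complete-linkage clustering under the
  uncentered correlation distance
  `1 − Σxy / (√Σx² √Σy²)` (cosine dissimilarity without mean-centering,
  range [0, 2]), the convention of classic expression-heat-map tools.
  Complete linkage guarantees monotone merge heights. Leaf order is the
  deterministic order produced by `stats::hclust`; the package asserts
  merge heights and cut partitions, not left–right orientation, so any
  platform-stable order serves.
* `deg_ak()` — progression DEGs between `AK_L` and `AK_NL` with the pooled
  t test at raw p < 0.05 and |FC| > 2. No multiplicity correction is
  applied by default for this contrast (a correction flag exists); the
  contrast is exploratory and its gene lists feed set-overlap summaries
  rather than confirmatory claims.
* `signature_overlap()` — the fraction of the progression signature also
  present in the SCC signature. The denominator is always the progression
  signature, so the measure is asymmetric by construction.
* `marker_trend()` — per marker, group means ± SD for the four stages NL,
  AK_NL, AK_L, L; one-way ANOVA; Tukey-HSD adjusted p for all six pairwise
  comparisons via the studentized-range distribution (classical
  equal-variance form); stars at 0.05 / 0.01 / 0.005.
* `grade_composition()` — whole-percent grade shares per subclass.

## The synthetic cohort

Real AK microarray cohorts are large, access-controlled downloads; the
package instead ships a generator (`generate_cohort()`) whose defaults
encode the study conditions the pipeline was designed around:

| parameter | default | meaning |
|---|---|---|
| `n_ref_patients` | 14 | paired reference patients (one NL + one L each) |
| `n_test_nl`, `n_test_l` | 9, 10 | held-out unpaired test samples (n = 19 is the size consistent with one misclassification ≈ 95 % and two ≈ 89 %) |
| `n_ak` | 21 | AK samples |
| `n_probes` | 2000 | probes (a desk-scale stand-in for a 60 k array) |
| `n_planted_degs` | 200 | probes with a true shift, half up / half down |
| `planted_log2fc` | 3 | planted absolute log2 fold change |
| `patient_effect_sd` | 1.0 | SD of the per-patient additive intercept (log2) |
| `noise_sd` | 0.5 | SD of i.i.d. Gaussian measurement noise (log2) |
| `ak_mixture_weights` | 12 in [0.05, 0.40], 9 in [0.60, 0.95] | AK j = w·L̄ + (1−w)·N̄L + noise |

Noise is i.i.d. Gaussian on the log2 scale — the simplest model consistent
with the t-test assumptions both routes make (microarray intensities are
approximately log-normal). The patient effect is an additive Gaussian
intercept shared by a patient's NL and L samples, which is exactly the
structure the paired model exploits and the unpaired t test wastes; with
`patient_effect_sd ≫ noise_sd` the paired route demonstrably recovers more
planted probes (a unit test). AK samples are convex mixtures of the
noise-free class mean profiles; the true subclass is `AK_L` when the
mixture weight is ≥ 0.5, matching nearest-centroid geometry in
expectation. Baseline probe means are drawn from N(7, 1.5²) log2 units,
typical of normalized array intensities.

Everything is driven by one RNG stream seeded from `seed`; cohorts are
pure functions of their parameters and the caller's RNG state is left
untouched.

What the generator does **not** emulate: probe-level dye and spatial array
artifacts, batch effects, intensity-dependent variance, correlated gene
modules, or RNA degradation. Passing tests therefore demonstrate that the
pipeline's logic is correct and recovers planted structure under its own
assumptions — not that the biological conclusions of any particular cohort
transfer. Note also one deliberate testing choice: the null-hypothesis
type-I-error check switches patient effects off, because a shared patient
intercept correlates a patient's NL and L samples and makes the unpaired
t test conservative by design rather than miscalibrated.

## Numerical choices and degenerate inputs

* Percentiles use linear interpolation between order statistics
  (`stats::quantile` type 7), stated so reimplementations can match.
* Quantile normalization resolves within-column ties by assigning the mean
  of the normalized values at the tied ranks. With that convention the
  operation is exactly idempotent on tie-free data; a tie in one column
  perturbs the pooled order-statistic distribution, so idempotence in the
  presence of cross-column ties is only approximate. The tests assert
  exact idempotence on continuous data and the tie convention on a hand
  example.
* Zero-variance probes: `p = 1`, not `NA`. Zero vectors are rejected by the
  uncentered-correlation distance (a direction-free item has no angle).
* Empty signatures abort the pipeline at the DEG stage with the route
  named; `select_pipeline()` refuses empty or size-mismatched reports.
* Exact centroid ties go to the NL side and are flagged.
* Monte-Carlo test sizes: property tests run 5–20 cohorts of 1000–2000
  probes — sizes at which every statistical property tested (sensitivity,
  FDR control, recovery rates, null calibration) is stable across seeds
  while the full suite stays fast.

## Known limitations

* The per-probe OLS t without variance moderation is noisier than a
  moderated statistic at very small n; it is kept because it makes the
  method fully self-contained and exactly reproducible from the model
  description.
* Distances in a 2-component plane discard any class separation living in
  later components; `distance_pcs = "retained"` is available but is not
  the default because the centroids are defined in the 2-PC plane.
* The progression contrast (`deg_ak()`) uses raw p-values by default and
  should be read as hypothesis-generating.
* The GEO series-matrix reader handles the common single-table layout
  only; it is an optional convenience, not a supported data path.
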