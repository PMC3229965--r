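---
title: "Building small CpG-signature age predictors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building small CpG-signature age predictors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylage)
```

## The problem and the model

Methylation at a CpG site, measured on Infinium arrays as a beta value
β ∈ [0, 1] (the intensity ratio of the methylated bead to the combined
locus intensity), changes with donor age at a minority of sites —
mostly slow, approximately linear gains at promoter-associated CpGs,
with occasional losses. `methylage` models each candidate site as

> β = A + B · age + ε,

with A the beta value extrapolated to age 0 (β units), B the drift rate
(β units per year; positive for age-hypermethylated sites, negative for
hypomethylated ones), and ε technical plus biological noise. Age
prediction inverts this *classical calibration*: the regression is
always fitted response-on-covariate (β on age) and then solved for age,

> Nᵢ = (βᵢ − Aᵢ) / Bᵢ,

one estimate per signature CpG *i*, averaged with equal weights into
the final prediction. The alternative — regressing age on β directly —
is a different estimator with different bias properties; this package
deliberately implements the calibration-then-invert form because that
is the estimator the shipped five-CpG signature was built with, and the
round trip β(age) → N(β) is then algebraically exact (a property the
test suite pins at 1e-10).

Assumptions worth stating explicitly: linearity of drift over the
observed age span; noise that is roughly symmetric and
age-independent; and signature sites whose drift direction and
magnitude are shared across tissues, so that one set of calibrations
can serve several cell types. None of these hold exactly on real
arrays; they hold well enough at strongly drifting sites, which is what
the selection filters are for.

## Screening: template matching

Screening correlates each CpG's β profile against a *template* — the
donor ages min–max scaled to [0, 1] (`build_age_template()`). Pearson
correlation is invariant under positive affine maps, so the scaling
changes nothing statistically (a property test asserts equality to
1e-12 against raw ages); it is kept because the template doubles as a
convenient plotting axis and matches how template-matching tools
present the profile.

Significance uses the exact null distribution of the sample
correlation under Gaussian errors: t = |r|·√((n−2)/(1−r²)) on n − 2
degrees of freedom, two-sided. At the 130-sample scale of a combined
five-dataset training group this gives the familiar anchors r = 0.6 ↔
p < 10⁻¹³ and r = 0.4 ↔ p < 10⁻⁵, which is why those two r thresholds
are the package defaults (`r_threshold = 0.6`,
`secondary_threshold = 0.4`). A test compares this t-based p against
the exact permutation distribution at n = 7 and finds agreement within
a factor of two for |r| < 0.8 — adequate for a screen that thresholds
on r, not p. No multiple-testing correction is applied to the retained
set (the threshold is on r); a Bonferroni column is emitted for
information only.

Screening operates on pairwise-complete samples per CpG, with a floor
`min_n = 8` (sites measured in fewer samples can reach |r| = 1 by
chance too easily), and never aborts on a degenerate row: a constant or
under-sampled CpG simply cannot be returned. Output order is |r|
descending with ties broken by probe ID, so results are deterministic.

## Selection: from candidates to a signature

The selection rule (`select_signature()`) encodes three published
criteria as a reproducible procedure:

* combined-set correlation (rank candidates by r over all training
  samples);
* per-dataset consistency — the candidate's per-dataset r must clear
  `min_per_dataset_r = 0.3` in at least a majority of datasets
  (`ceiling(n_datasets/2)`, i.e. 3 of 5 for the canonical design),
  because a combined-set correlation can be an artifact of unequal age
  distributions across cohorts;
* dynamic range — the fitted |Δβ| between the youngest and oldest
  donor must reach `min_range = 0.05` β units, since small absolute
  drifts are dominated by technical noise even when well correlated.

The defaults are judgment calls where the original selection was
partly judgment ("comparison of age-predictions in the training set");
they are chosen so the procedure is monotone (tightening either floor
can only shrink the eligible set — a property test) and so that, on the
synthetic benchmark below, planted CpGs are retrieved with precision
and recall 1.0. Users reproducing the published predictor should not
re-derive it: `published_signature()` ships the five probes (and the
three-probe variant) as frozen constants, pinned by a test.

One probe-ID discrepancy is worth recording: the NPTX2 probe circulates
in two spellings, a 9-digit `cg1279989` and the 10-character
`cg12799895`. Only the latter is a valid Illumina probe identifier, so
the package uses `cg12799895`.

## Calibration, prediction, evaluation

`fit_cpg_calibration()` is ordinary least squares via `stats::lm`, one
line per signature CpG over all training samples. A slope floor guards
the inversion: |B| < 10⁻⁴ β/yr flags the calibration *degenerate* and
excludes it from prediction (inverting a near-flat line turns
milli-unit noise into decades of error). Predictions are *not* clamped
by default — raw estimates may be negative or exceed a lifespan, which
is informative scatter — but `clamp = TRUE` bounds them to [0, 120]
years. Missing signature betas in a test sample are averaged over, with
`n_cpgs_used` recorded; a sample missing every signature probe is an
error, not a silent NA.

Why averaging helps: each single-CpG estimate carries error ε/B, so
with independent noise its mean absolute error is (σ/|B|)·√(2/π) (the
folded-normal mean). Averaging k such estimates shrinks the error
roughly by √k. Both facts are verified by simulation in the acceptance
suite (n = 1000 samples, 20 seeds, 5% tolerance on the folded-normal
prediction), and the averaged predictor is required to beat every
single CpG.

`evaluate_predictions()` reports precision as the mean absolute
difference between predicted and chronological age (the "± years"
convention of the epigenetic-clock literature) alongside the r² of
predicted versus actual age.

## The synthetic cohort generator

`generate_cohort()` emulates the structure of the canonical
five-dataset training design so every stage is testable without array
downloads. The frozen default (`training_cohort_spec()`) mirrors that
design's sample sizes and age ranges: dermis 20 (18–72 yrs), epidermis
30 (19–72), cervical smear 30 (26–43), CD4 T-cells 24 (16–69), CD14
monocytes 26 (16–69) — 130 samples. Planted signature CpGs follow
`clip(A + B·age + offset + noise, 0, 1)` with slopes drawn from
0.002–0.006 β/yr (the magnitude of strong age-drift sites; sign flipped
for the hypomethylated CpG), intercepts placed so the line stays inside
[0.05, 0.95] over the age span (keeping clipping inactive, so OLS
recovery is unbiased), 500 null CpGs with no age term, Gaussian
measurement noise with SD 0.03 (a modeling choice on the order of
Infinium technical replicate scatter; the true per-site cohort variance
is not published as a number), and per-dataset tissue offsets with SD
0.01 emulating tissue-specific baselines. Ages are uniform within each
dataset's range — ranges and medians are all that is published, and
uniform is the least-assumption choice; medians are not matched.

Seeding is counter-based: one master integer seed, with each dataset's
draws (and the planted-CpG parameters) derived from an independent
sub-seed, so reordering or adding datasets never perturbs the others'
draws, and the same `truth` can be reused to generate an independent
validation cohort from the same planted model.

What the generator does *not* emulate — genome-wide beta bimodality,
probe-chemistry effects, CpG–CpG correlation, batch structure,
non-uniform age sampling — bounds what green tests mean: they show the
estimator and its implementation are correct under the stated model,
not that real-array precision will match. On real multi-tissue data the
published predictor's error is on the order of ten years; on the
synthetic model with noise SD 0.03 it is 2–4 years, the gap being
exactly the biology and batch structure the generator leaves out.

## Numerical and design choices

* **Quantiles** (`quantile_summary()`): linear interpolation between
  order statistics (`stats::quantile` type 7), monotone in the level by
  construction.
* **Combining datasets**: probe-set *intersection* (safe under mixed
  platforms), first matrix's probe order, samples concatenated in input
  order; duplicate sample IDs are an error. No normalization, ever.
* **Missingness**: explicit NA carried through all stages;
  pairwise-complete samples per CpG downstream. Array repositories ship
  masked probes, so silent dropping is never acceptable.
* **Serialization**: beta matrices and fitted models are written with
  17 significant digits, so write → read round trips are bit-exact
  (parsing goes through base R's correctly rounded `strtod`).
* **Determinism**: identical inputs and config produce byte-identical
  output files; timestamps live only in logs, never in artifacts.
* **Probe masking**: no default exclusion of X-chromosome or otherwise
  masked probes is applied before screening; callers with a mask should
  filter rows beforehand.

## Problem sizes used in the test suite

Oracle-equivalence and property tests run on matrices up to 50 CpGs ×
20 samples against brute-force loops; recovery statistics use the full
130-sample, 505-CpG frozen design over 100 seeds; the folded-normal
error law is checked at n = 1000 over 20 seeds. These sizes give the
binomial/SE margins the assertions need (e.g. 500 slope fits for a
≥ 99% 3-SE coverage bound) while keeping the suite fast.

## Known limitations

Chronological age is not biological age; part of any real residual is
that difference, not noise. The linear-drift model saturates at sites
approaching β near 0 or 1, which the clip in the generator acknowledges
but the calibration does not model. Single-tissue calibrations applied
to other tissues inherit tissue offsets as bias — the per-dataset
consistency filter reduces, but does not eliminate, this. And the
package deliberately stops short of multivariate or penalized clocks
(elastic-net style predictors over hundreds of CpGs): its scope is the
small-signature, inverse-calibration design, where every coefficient
remains interpretable.
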