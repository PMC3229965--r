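# methylage

Small CpG-signature epigenetic clocks from Infinium beta values.

DNA methylation at specific CpG sites drifts steadily with age — some
promoter-associated sites gain methylation over a lifetime, a few lose
it — and the drift is consistent enough across tissues that a handful of
sites suffices to estimate a donor's age from a single methylation
profile, for example in forensic analysis of an unknown blood or tissue
specimen. `methylage` implements the complete workflow for building and
applying such a predictor from beta-value matrices (fraction methylated,
β ∈ [0, 1], probes in rows, samples in columns, as HumanMethylation27
series matrices ship):

1. **Combine** datasets from several tissues on the probe reference ID,
   deliberately without cross-dataset normalization (genuine
   between-tissue methylation differences would be masked by it).
2. **Screen** every CpG by template matching: each probe's β profile is
   Pearson-correlated against a donor-age template (ages min–max scaled
   to [0, 1]); sites with r above a threshold are age-associated
   candidates. Significance comes from the exact null distribution of
   the sample correlation, `t = |r|·√((n−2)/(1−r²))` on `n − 2` df,
   two-sided.
3. **Select** a compact signature: candidates must correlate with age in
   the combined set *and* in a majority of the individual datasets, and
   must span a sufficient methylation dynamic range (fitted |Δβ| between
   the youngest and oldest donor), because larger changes are less prone
   to technical noise.
4. **Calibrate and predict** by classical inverse regression: per CpG
   *i*, OLS of β on age gives `βᵢ = Aᵢ + Bᵢ·age`; a new sample's age
   estimate from that CpG is `Nᵢ = (βᵢ − Aᵢ)/Bᵢ`, and the predicted age
   is the unweighted mean of the Nᵢ over the signature CpGs.
5. **Evaluate** precision as the mean absolute difference between
   predicted and chronological age (years), plus the r² of predicted
   versus actual age.

The published five-CpG aging signature — TRIM58 (cg07533148), KCNQ1DN
(cg01530101), NPTX2 (cg12799895) and GRIA2 (cg25148589)
hypermethylated, BIRC4BP (cg23571857) hypomethylated — ships as frozen
constants (`published_signature("five")`, with a `"three"` variant), and
a synthetic cohort generator with planted age-associated CpGs makes the
whole pipeline testable without downloading any array data.

Everything is tidyverse-native: beta matrices and annotations are
tibbles, every stage returns a tibble (or an object with broom-style
`tidy()`/`glance()` methods), and `autoplot()`/`plot_*()` functions give
ggplot2 views of calibrations, quantile distributions and predictions.

## Worked example

A synthetic training cohort mirroring the five-tissue training design
(dermis, epidermis, cervical smear, CD4 T-cells, CD14 monocytes; 130
samples; 4 hypermethylated + 1 hypomethylated planted CpG among 500 null
CpGs; noise SD 0.03):

```r
library(methylage)

cohort   <- generate_cohort(training_cohort_spec(seed = 42))
template <- build_age_template(cohort$annotations)
hits     <- run_ptm(cohort$beta, template, r_threshold = 0.6,
                    direction = "both")
hits
#> # A tibble: 5 × 6
#>   cpg_id          r        p n_used direction p_bonferroni
#>   <chr>       <dbl>    <dbl>  <int> <chr>            <dbl>
#> 1 cg00000005 -0.942 1.62e-62    130 hypo          8.16e-60
#> 2 cg00000001  0.928 6.47e-57    130 hyper         3.27e-54
#> 3 cg00000003  0.928 1.50e-56    130 hyper         7.56e-54
#> 4 cg00000004  0.918 3.15e-53    130 hyper         1.59e-50
#> 5 cg00000002  0.847 5.45e-37    130 hyper         2.75e-34
```

Only the five planted CpGs clear r = 0.6; all 500 age-independent
probes are rejected (the null tail probability of |r| ≥ 0.6 at n = 130
is below 10⁻¹³ per probe). Per-dataset consistency, selection, and
calibration:

```r
per_ds <- per_dataset_ptm(cohort$beta, cohort$annotations, hits$cpg_id)
sig    <- select_signature(hits, per_ds, cohort$beta, cohort$annotations,
                           k_hyper = 4, k_hypo = 1)
model  <- fit_signature_model(cohort$beta, cohort$annotations, sig)
tidy(model)
#> # A tibble: 5 × 9
#>   cpg_id     intercept    slope slope_se r_squared n_train degenerate role
#>   <chr>          <dbl>    <dbl>    <dbl>     <dbl>   <int> <lgl>      <chr>
#> 1 cg00000001    0.255   0.00552 0.000195     0.862     130 FALSE      hyper
#> 2 cg00000003    0.0908  0.00513 0.000183     0.860     130 FALSE      hyper
#> 3 cg00000004    0.108   0.00443 0.000169     0.843     130 FALSE      hyper
#> 4 cg00000002    0.178   0.00361 0.000200     0.718     130 FALSE      hyper
#> 5 cg00000005    0.852  -0.00608 0.000192     0.887     130 FALSE      hypo
```

Each row is one calibration line `β = A + B·age`: e.g. cg00000001 starts
near β = 0.26 at birth and gains 0.0055 β-units per year. Predict an
independently generated validation cohort (same planted model, new
donors and noise) and evaluate:

```r
val    <- generate_cohort(training_cohort_spec(seed = 43),
                          truth = cohort$truth)
report <- evaluate_predictions(predict_age(model, val$beta),
                               val$annotations)
report
#> <precision_report> n = 130  mean |error| = 2.538 yrs  r^2 = 0.955
```

Predicted ages deviate from the true donor ages by 2.5 years on average
under this noise model. `plot_predictions(report)` draws the
predicted-versus-actual scatter; `autoplot(model, cohort$beta,
cohort$annotations)` overlays the calibration lines on the training
data.

The same workflow is scriptable from a shell via `exec/methylage`
(`simulate`, `screen`, `fit-predict-evaluate` subcommands) or from R via
`run_screen()` / `run_fit_predict_evaluate()`, which enforce the
train/test split structurally and write all tabular artifacts plus a
machine-readable run manifest.

## Applying the published signature to real arrays

`published_signature("five")` gives the probe set; feed any beta matrix
containing those probes to `fit_signature_model()` (on a training cohort
with known ages) and `predict_age()` (on new samples). Public
HumanMethylation27 accessions (GEO / ArrayExpress series matrices) can
be exported to the package's TSV dialect by stripping the series-matrix
header down to the probe-by-sample table; no downloader is bundled, so
that analysis remains an optional, network-dependent exercise.

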