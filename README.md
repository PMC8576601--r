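# actidep

Digital biomarkers and depression screening from consumer-wearable streams.

Depressive symptoms leave traces in everyday behavior and physiology:
irregular rest–activity rhythms, later sleep timing, and altered nocturnal
heart-rate dynamics. `actidep` implements a complete, reproducible pipeline
that extracts ~122 interpretable digital biomarkers from tracker streams —
minute-level steps and METs, 5–10-second heart rate, 30-second sleep stages
— and evaluates them as a screen for depressive symptoms measured by two
PHQ-9 assessments. It is aimed at researchers in digital phenotyping and
behavioral epidemiology who want the full chain, from raw streams to
cross-validated classification, as tested R functions.

The pipeline:

1. **Quality control** — device use time verified from heart-rate coverage
   (a minute is complete iff it contains a heart-rate sample), days kept at
   ≥20 complete hours, participants at ≥10 complete days and ≥3 weekday
   sleep nights, Tukey 1.5·IQR outlier exclusion on mean heart rate and
   daily steps.
2. **Biomarkers** — activity (steps, MET intensity bands, sedentary time),
   sleep (TST, SE, SOL, middle-half WASO, offset/midpoint timing with CVs),
   circadian rhythm (interdaily stability IS, intradaily variability IV,
   interdaily coefficient of variation ICV, M10/L5 and relative amplitude
   `RA = (M10−L5)/(M10+L5)`, day-lag autocorrelation at 15/30/60-minute
   aggregation, z-score peak counts, and the extended cosinor
   `y(t) = min + amp·F(cos(2π(t−φ)/24))` with the anti-logistic transform
   `F(c) = 1/(1+e^{−β(c−α)})`, reporting mesor, amplitude, acrophase, α, β
   and a pseudo-F), and heart rate (resting HR from zero-step windows,
   delta HR, 2–4 PM and 12–2/2–4/4–6 AM window statistics, RMSSD).
3. **Associations** — Spearman screen against the average PHQ-9 score with
   Benjamini–Hochberg FDR control, and block-nested covariate-adjusted
   linear regression.
4. **Screening models** — correlation-threshold feature selection frozen on
   the full sample, DART gradient boosting, stratified 4-fold × 25-repeat
   cross-validation, confusion-matrix metrics with Cohen's κ and
   Mann–Whitney AUC, and contrasted subsampling (screen-positive vs
   minimally symptomatic participants) under four PHQ-9 cutoff rules.

A synthetic-cohort simulator (`generate_cohort()`) produces realistic
streams — bimodal weekday activity with habitual exercise bouts,
activity-coupled AR(1) heart rate, semi-Markov sleep staging, contiguous
non-wear gaps, test–retest-correlated PHQ-9 totals — with plantable group
effects (lower IS, higher 4–6 AM heart-rate variation, fewer step peaks,
later sleep midpoint), so the whole pipeline is testable end to end without
any data download.

## Worked example

```r
library(actidep)

cfg <- cohort_config(
  n_participants = 80, days_per_participant = 14,
  depressed_fraction = 0.25,
  effect_sizes = list("IS.st.wd" = -1, "NHR.0406.cv" = 1),
  seed = 42
)
cohort <- generate_cohort(cfg)
feats  <- biomarker_matrix(cohort)          # QC + extraction
oc     <- cohort$outcomes[match(feats$id, cohort$outcomes$id), ]

screen <- spearman_screen(feats, oc$phq9_avg)
head(screen[order(screen$q), ], 3)
#> # A tibble: 3 × 5
#>   biomarker     rho        p            q     n
#>   <chr>       <dbl>    <dbl>        <dbl> <int>
#> 1 NHR.0406.sd 0.708 1.76e-10 0.0000000215    61
#> 2 ICV.st.wd   0.667 4.33e- 9 0.000000264     61
#> 3 ICV.hr      0.538 7.68e- 6 0.000312        61
```

Of the 80 simulated participants, 61 survive the completeness cascade. The
screen's top hits carry the planted signs and sit in the planted families:
4–6 AM heart-rate variation (`NHR.0406.sd`, ρ = 0.71) and step-rhythm
instability (`ICV.st.wd` — the interdaily coefficient of variation rises as
the planted stability falls) track the PHQ-9 average, and the planted
markers themselves follow immediately after. A classification model on the
contrasted rule-A subsample (PHQ-9 ≥10 at either assessment vs minimally
symptomatic participants):

```r
sub <- contrasted_subsample(oc, "A", seed = 42)
x   <- feats[match(sub$id, feats$id), select_features(screen, "A")]
fit <- cv_classify(x, sub$label, seed = 42)
fit$performance
#> # A tibble: 8 × 3
#>   metric       mean     sd
#>   <chr>       <dbl>  <dbl>
#> 1 nir         0.538 NA    
#> 2 accuracy    0.680  0.171
#> 3 sensitivity 0.597  0.273
#> 4 specificity 0.753  0.234
#> 5 ppv         0.704  0.272
#> 6 npv         0.701  0.188
#> 7 kappa       0.350  0.350
#> 8 auc         0.765  0.196
```

Mean holdout accuracy of 68% against a 54% no-information rate, with κ ≈
0.35 and AUC ≈ 0.77 — a clear but modest signal, as expected from a small
contrasted subsample at one-SD planted effects; larger cohorts or stronger
effects (see the acceptance script) separate the groups further.
`run_pipeline(pipeline_config(...))` wraps the same chain and writes the
feature matrix, association table, performance tables and a manifest
(config, seeds, file hashes) to an output directory; reruns with the same
config and seed are byte-identical.

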