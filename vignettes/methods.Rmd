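---
title: "Digital biomarkers of depression from consumer wearables: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital biomarkers of depression from consumer wearables: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actidep)
```

## The problem

Consumer fitness trackers record, for weeks at a time, minute-level step
counts and energy expenditure (METs), heart rate every few seconds, and
30-second sleep-stage epochs. `actidep` turns those streams into a roster of
~122 interpretable *digital biomarkers* — physical activity, sleep timing and
quality, circadian rhythm regularity, nocturnal heart-rate physiology — and
asks whether they can screen for depressive symptoms measured by the PHQ-9
(a 9-item questionnaire scored 0–27, with ≥10 the conventional
screen-positive cutoff, administered twice ~2 weeks apart).

The pipeline has five stages: completeness-based quality control, biomarker
extraction, univariate Spearman screening with false-discovery-rate control,
covariate-adjusted hierarchical regression, and cross-validated
gradient-boosted classification under several PHQ-9 cutoff rules. Because no
real cohort ships with the package, a synthetic-cohort simulator generates
wearable streams with known, plantable group effects; every downstream claim
the test suite makes is a claim about recovering what the simulator planted.

## Quality control

Device use time is verified from heart rate, the channel most sensitive to
non-wear: a minute is *complete* iff at least one heart-rate sample falls in
it (5-second devices yield 12 samples per minute, 10-second devices 6, so
completeness is defined per time point rather than per sample count).
Activity and sleep samples outside complete minutes are discarded. A day
enters the analysis with ≥20 complete hours (boundary inclusive); a
participant with ≥10 complete days and ≥3 weekday sleep nights. Participant
means of heart rate and daily steps are then screened by the Tukey fence
(1.5 × IQR beyond the quartiles, type-7 linear-interpolation quartiles —
the convention is pinned because the rule is quartile-sensitive). Days are
local midnight-to-midnight; partial first/last days qualify only if they
meet the hour threshold.

## The biomarkers

**Activity.** Mean daily steps and sedentary minutes (all days, weekdays,
weekends), and mean daily minutes of light, moderate and vigorous activity
by MET bands: moderate 3.0–6.0 METs, vigorous >6.0, sedentary ≤1.5 while
awake. "Light" is operationalized as the waking band (1.5, 3.0): the common
"below 3.0" phrasing overlaps the sedentary definition, so the bands are
made disjoint and documented.

**Sleep.** Contiguous staged runs form device sleep records; for each night
the longest record overlapping 8 PM–noon is the main episode (naps are
dropped). Per episode: time in bed (epochs × 0.5 min), TST (TIB − wake), SE
(TST/TIB), sleep-onset latency (time to first non-wake epoch), and WASO
counted *only in the positional middle half* of the episode (zero-based
epoch indices in `[N/4, 3N/4)`, floored). Episodes are assigned to the
calendar day of the offset — the wake-day — so the weekday flag refers to
the workday the night precedes. Offset and midpoint are expressed in hours
since midnight of the wake-day; pre-midnight onsets contribute negative
hours to the midpoint average, which avoids wrap-around artifacts.

**Circadian rhythm.** From hourly-aggregated steps and heart rate (all days
and weekdays-only): interdaily stability
`IS = N Σ_h (x̄_h − x̄)² / (p Σ_i (x_i − x̄)²)`, intradaily variability
`IV = N Σ (x_i − x_{i−1})² / ((N−1) Σ (x_i − x̄)²)`, the interdaily
coefficient of variation (mean over the 24 hours of the across-day SD/mean
of each hour), M10/L5 (most/least active consecutive hours of the average
day, searched circularly) with `RA = (M10 − L5)/(M10 + L5)`, and day-lag
autocorrelation at 15/30/60-minute aggregation using the full-sample
denominator (numerator over the N−k pairs, denominator over all N; a
pair-count-normalized variant sits behind a flag). Hours with no complete
minutes propagate as missing and the formulas use available values only.

Peaks are counted by the streaming z-score detector: a point deviating from
the trailing moving mean by more than `threshold` trailing SDs over `lag`
points is signaled, signaled points enter the trailing statistics with
weight `influence`, and contiguous upward runs count as one peak. Defaults —
15-minute bins, `lag = 12` (3 h), `threshold = 2`, `influence = 0.1` — are
package choices (the algorithm's source does not prescribe them) and are
configurable.

The extended cosinor fits
`y(t) = min + amp · F(cos(2π(t − φ)/24))`, `F(c) = 1/(1 + e^{−β(c−α)})`,
by Levenberg–Marquardt least squares: α is the relative width of the peak
(bounded to (−1, 1)), β the steepness of rise and fall (positive), the mesor
is the mean of the fitted curve over the day, the amplitude the curve
maximum minus the mesor, and the acrophase the clock time of the peak
wrapped to [0, 24). Goodness of rhythm is the pseudo-F against the constant
model, `((SS0 − SSR)/(q − 1))/(SSR/(n − q))` with q = 5. The acrophase is
multi-started on the grid {0, 6, 12, 18}; starts are ranked by initial SSR
and the two best are optimized fully (tolerance 1e-8). Fits that stop at the
iteration cap with a parameter pinned at its bound but a flattened SSR trace
are accepted — the optimizer reports the cap when a parameter rides a bound.
Constant series are degenerate and error; non-convergence yields missing
features.

**Heart rate.** Resting heart rate is the mean over calendar-aligned,
non-overlapping 15-minute windows with zero steps; delta HR is overall mean
minus RHR. Daytime (2–4 PM) and nighttime (12–2, 2–4, 4–6 AM) windows yield
per-day mean/SD/CV, computed per night and then averaged (a pooled mode is
available behind a flag; the per-night default keeps nights exchangeable).
Night windows are the early-morning hours of the wake-day, i.e. they belong
to the night preceding it. RMSSD is computed on the raw 5-second samples and
on the hourly means, with gaps breaking successiveness. The overall mean
weights each complete minute equally so 5- and 10-second devices are
comparable.

## The synthetic cohort

`generate_cohort()` draws, per participant: a smooth two-peak (commute-like)
weekday step template and a flatter weekend variant scaled by a log-normal
person effect; discrete activity bouts at per-participant *habitual* clock
times with night-to-night timing jitter; negative-binomial minute step
counts (variance > mean); METs coupled to steps; heart rate as a personal
baseline plus a smooth circadian day lift, an activity-coupled increment
(0.22 bpm per step/min) and AR(1) noise at 5-second sampling; one nightly
semi-Markov sleep episode over wake/light/deep/REM; and contiguous non-wear
blocks that remove heart rate first. PHQ-9 totals arise from a gamma-skewed
latent severity plus independent assessment noise whose SD is set from the
configured test–retest correlation (default 0.73); a fixed 1.07 inflation
compensates the correlation gain caused by clipping totals at 0. Covariates
(age, gender, ethnicity, marital status, education, income, alcohol,
smoking, self-rated health, and loneliness/sleep-questionnaire totals) are
drawn to match the marginal frequencies of a working-adult cohort, with mild
coupling of loneliness and sleep quality to severity so adjustment is
non-trivial.

Habitual bout times are the one structural choice that deserves comment:
with fully random bout times, bout placement dominated the between-day
variance, so removing bouts *raised* interdaily stability by more than the
irregularity knob could lower it, and planted effects contaminated each
other. Anchoring bouts to stable personal times moves their variance into
the daily profile, where it belongs behaviorally, and decouples the knobs.

Planted effects (per `supported_effects()`) follow a dose-response in the
latent severity that also generates the PHQ-9 totals: each participant
receives the configured effects multiplied by their standardized severity
(clamped at ±2.5), so biomarkers track the severity continuum instead of
jumping at an arbitrary group boundary — the statistical structure a
correlational analysis of a continuous score presumes, and the reason the
Spearman screen can recover planted markers reliably. The depressed
subgroup, drawn from a higher severity distribution, ends up with a group
contrast of about twice the configured value. The knobs themselves: rhythm
irregularity inflates the daily template phase shift, the hourly jitter and
the bout-time jitter; nighttime heart-rate variation scales the AR(1) noise
inside 4–6 AM (applied as a multiplier *after* the draws, so paired
comparisons under one seed differ only there); peak count scales bout rate
and intensity; sleep midpoint shifts the whole schedule in hours. The
calibration constants mapping a unit effect at one severity SD to ≈1
cohort-SD shift of the targeted biomarker were fixed once from dedicated
calibration runs at `depressed_fraction = 0.5`, n = 80, and are not tuned
thereafter.

Default conditions: 14 tracking days starting on a Monday, 85% wear
compliance, 15% depressed fraction. The non-wear mix (a ~70-minute daily
routine gap plus occasional long device-off stretches) reproduces the
realistic feature that ~78% of days reach 20 complete hours; with only 14
days of tracking this leaves ≈70–80% of participants clearing the 10-day
rule, lower than a study tracking ~18 days would retain — the three
compliance statistics cannot all be matched at 14 days, and day-level
fidelity was preferred. The generator emulates diurnal structure, wear gaps
and planted group differences; it does not emulate device firmware noise,
REM architecture, naps (off by default), weather/seasonal trends, or the
heavy inter-individual heterogeneity of real free-living data — so passing
recovery tests shows the pipeline is correct and sensitive, not that real
cohorts will yield the same effect sizes.

## Statistics and models

The univariate screen is Spearman rank correlation (midrank ties, asymptotic
two-sided p — appropriate at cohort n; pairwise-complete observations,
features with <10 pairs or no variance excluded) against the average of the
two PHQ-9 totals, with Benjamini–Hochberg adjustment across the roster.
Hierarchical regression adds covariate blocks cumulatively
(sociodemographics; alcohol/smoking/self-rated health; loneliness and sleep
questionnaires), with fixed reference levels and listwise deletion; a
`per_10pct` option rescales coefficients of proportion-like biomarkers
(IS, AC, CV) to a 0.10 change of their unit scale.

Classification labels follow four cutoff rules: A — total ≥10 at either
assessment; B — ≥8 at both; C — average ≥8; D — top vs bottom 20% by
average (ties broken by participant id). Contrasted subsamples pit the
rule's depressed group against minimally symptomatic participants (average
in (0, 4], zero averages excluded for response-honesty concerns), matched in
size (rule A keeps two extra healthy participants, mirroring the 38 vs 40
shape; rule D uses the ranges 7.5–14 vs 0.5–1.5 and downsamples the larger
side). Feature selection (rule A: p < .01; B: p < .05; C: .01 ≤ p < .05 on
the raw screen p values) is frozen on the full sample and reused unchanged
in every subsample model, so the selected set cannot adapt to a particular
subsample's composition.

Models are gradient-boosted trees with the DART booster. The hyperparameters
are fixed, not tuned: depth 3, 200 rounds, learning rate 0.1, drop rate 0.1,
single-threaded with seeded fold assignment and booster RNG so that any run
is bit-reproducible. Evaluation is stratified repeated k-fold
cross-validation with 4 folds and 25 repeats — 4 folds puts 25% of the
sample in each holdout, the usual test-set fraction. Per holdout fold the
confusion matrix at probability 0.5, the rank-based (Mann–Whitney) AUC and
the no-information rate are computed; metrics are averaged over the 100
folds (per-fold averaging, not pooled predictions; a pooled mode exists
behind a flag). Degenerate divisions (e.g. PPV with no positive calls)
propagate as NA rather than 0. Stratification defaults to on everywhere; a
flag disables it. Feature importance is gain-based, normalized to sum to 1
and averaged across all fitted ensemble members.

## Numerical conventions and edge cases

Constant series make IS/IV/AC undefined (missing, not zero); hours with zero
across-day mean are skipped in ICV with the divisor reduced and a warning;
`RA` is missing when `M10 + L5 = 0`; an all-wake sleep episode has no onset
and is dropped with a warning; an empty heart-rate stream yields zero
complete days rather than an error; and timing features require ≥3 nights
(≥3 weekday nights for the weekday variants, matching the inclusion rule).
CVs require a positive mean. All aggregation grids are calendar-aligned so
results do not depend on recording phase.

## Problem sizes in the test suite

The suite exercises the formula implementations against independent
brute-force oracles (hundreds of random small instances, agreement to 1e-12
relative), and the pipeline properties on simulated cohorts: planted-effect
recovery uses 20 cohorts of n = 200 over 14 days; the contrasted
classification property uses one n = 260 cohort with strong (±1.5) planted
effects, giving a rule-A contrasted subsample of about a hundred
participants; reproducibility is checked
byte-for-byte on a 24-participant, 7-day configuration. These sizes are the
package's chosen compromise between statistical resolution and a test suite
that runs in minutes on one core.

## Known limitations

Fold-level AUC on small holdouts (~20 participants) is noisy; per-10%-change
coefficient scaling is a convention, not an estimand; the simulator's
depressed group differs from its healthy group only through the planted
knobs plus the severity shift, so null-feature false-positive rates are
cleaner than in real data; and the 20-hour/10-day/3-night inclusion cascade,
while faithful to its sources, interacts with the 14-day default tracking
length as noted above.
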