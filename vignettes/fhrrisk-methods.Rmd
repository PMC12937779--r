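---
title: "Methods: FHR feature extraction and preterm risk stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FHR feature extraction and preterm risk stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fhrrisk)
```

## The problem

Antepartum cardiotocography records the fetal heart rate (FHR) through an
abdominal ultrasound transducer. In preterm pregnancies (27+0 to 36+6 weeks)
the clinical question is whether a trace carries evidence of fetal
compromise severe enough to justify intervention. Visual interpretation is
unreliable, so computerised systems reduce a trace to a small set of
physiologically validated features and base decisions on those. `fhrrisk`
implements that full analysis chain as a reusable, testable pipeline:
simulate traces with known ground truth, extract seven Dawes-Redman-style
features, apply plausibility and cohort-construction filters, build a
matched and stratified modelling dataset, train and compare six classifier
families, and evaluate the final risk model by discrimination, calibration,
operating thresholds and decision-curve net benefit.

Because the clinical data such models are built on cannot be redistributed,
the package is organised around a synthetic-data generator whose planted
ground truth makes every downstream stage verifiable: event detection is
checked against planted events, cohort feature medians against configured
targets, and the modelling stack against planted class separation.

## The seven features

All features are computed on the first 60 minutes of a trace (`cap_min`),
on non-missing samples only.

* **Basal FHR (bpm)** — time-average of the fitted baseline.
* **Accelerations (count)** — maximal runs at least 10 bpm above baseline
  lasting longer than 15 s.
* **Decelerations (count)** — maximal runs at least 10 bpm below baseline
  that either contain at least 20 bpm below baseline sustained for more than
  30 s, or last more than 60 s.
* **Most lost beats (beats)** — the largest per-deceleration area between
  baseline and signal (bpm x minutes). For a rectangular dip this is depth
  times duration; the integrated-area form is well defined for any
  morphology.
* **Short-term variation, STV (ms)** — mean absolute difference between
  successive epoch-level pulse intervals (60000 / FHR).
* **Minutes of high / low variation** — minutes whose epoch pulse-interval
  range is at or above 32 ms (high) or at or below 30 ms (low), counted only
  inside episodes of at least 5 qualifying minutes in any 6 consecutive.

### Numerical choices

The one-line clinical definitions leave several quantities open; the
package fixes them as follows and exposes every value in
`feature_params()`:

* **Baseline** (`fit_baseline`): iterative trimmed moving average — a
  centred 10-minute windowed mean from which samples deviating more than
  10 bpm from the current estimate are excluded, iterated to convergence
  (tolerance 0.1 bpm, at most 20 iterations). This matches the notion of
  "the average FHR excluding major deviations": a planted 60-s, 30-bpm
  deceleration moves the estimate by well under 2 bpm. Windows shrink at
  the trace edges; gaps where every sample is trimmed or missing are filled
  by linear interpolation.
* **STV epoching**: 3.75-s epochs (16 per minute), epoch value = mean pulse
  interval of the epoch's non-missing samples. A raw per-sample definition
  would scale with the monitor's output rate; the 3.75-s epoch is the
  standard computerised-CTG convention and makes STV sampling-rate
  invariant. Epochs overlapping a detected deceleration are excluded, as
  are epochs in minutes with more than 50% signal loss; differences are
  taken between adjacent valid epochs only.
* **Episode thresholds**: minute range of epoch pulse intervals >= 32 ms
  (high) / <= 30 ms (low); episode persistence 5-of-6 minutes, extended
  maximally. These are the published computerised-CTG conventions; both
  thresholds and the persistence rule are configuration.
* **Gap bridging**: sub-threshold interruptions shorter than 5 s inside an
  event run are bridged, so sampling noise does not split one physiological
  event in two.
* **Missingness**: minutes with more than 50% missing samples are excluded
  from STV and episode classification, preventing signal loss from
  masquerading as low variation. Signal loss itself is reported as the
  percentage of missing samples in the analysed window.

Two consequences of these definitions are worth stating because they
constrain what group-level feature values are attainable at all:

* a detected deceleration cannot lose fewer than about 11 beats (the
  shallowest qualifying dip is ~10 bpm for just over a minute, or ~20 bpm
  for just over half a minute), so a cohort in which most traces have no
  deceleration cannot have a nonzero most-lost-beats median below that; and
* episode minutes come in blocks of at least 5, so per-trace episode
  minutes are either 0 or >= 5 and cohort medians between 1 and 4 are
  unreachable.

The generator's default targets (below) respect both constraints.

Note also that STV lives on the pulse-interval scale: adding a constant c
bpm to every sample of a trace leaves event counts, lost beats and episode
minutes unchanged and shifts the basal rate by exactly c, but rescales STV
by roughly (b/(b+c))^2 — the pulse-interval increments shrink as the rate
rises. The tests check the invariances in exactly this form.

## The synthetic-data generator

`simulate_trace()` builds each trace from planted ground truth
(`PlantedTruth` is returned alongside the trace) so that extraction can be
validated event-by-event and minute-by-minute.

* **Baseline trajectory**: a per-trace level drawn around the cohort's
  basal target (sd 3.5 bpm), a slow linear drift (within +/- 3 bpm) and up
  to three small mean-centred steps, clipped to [100, 180] bpm.
* **Variability** is generated on the pulse-interval scale, where STV is
  defined. Each minute is assigned a behavioural state — high variation,
  low variation, or intermediate — and its 16 epoch pulse-interval
  deviations are a slow sinusoidal oscillation (fetal behavioural cycling,
  rate solved per trace, typically ~2 cycles/min) plus an AR(1) jitter,
  rescaled so the minute's epoch range is pinned exactly: high-state
  minutes at 36-56 ms, low-state at 14-26 ms and intermediate minutes at
  30.4-31.6 ms, i.e. inside the dead band between the low (30 ms) and high
  (32 ms) thresholds. The pinning is what makes episode minutes exactly
  controllable: only planted blocks qualify, and the 5-of-6 persistence
  rule never assembles an episode out of stray minutes. The cycling rate is
  solved in closed form so the mixture of states reproduces the per-trace
  STV target (the closed-form sinusoid prediction is attenuated by a
  measured factor 0.955 for per-minute rescaling and minute-boundary
  discontinuities; acceleration epochs, which stay in the STV computation,
  are debited analytically from the target before solving).
* **Episodes**: a per-trace block of high-variation minutes with median
  length equal to the cohort target (log-normal spread, minimum 5), placed
  away from other planted structure; cohorts with a zero target still carry
  a short episode with configurable probability (defaults 0.4 high / 0.3
  low) so the upper quartiles look realistic.
* **Events**: acceleration and deceleration counts are Poisson with medians
  equal to the cohort targets. Accelerations are Tukey-windowed bumps of
  19-28 bpm lasting 28-45 s — the lower amplitude bound clears the 10-bpm
  detection threshold by more than the largest variability excursion, so
  planted events are recovered exactly. Decelerations are rectangular dips
  whose depth (23-32 bpm) and duration are derived from the trace's
  most-lost-beats target (about 0.6 beats of the extracted area comes from
  adjacent variability dips and is debited in advance); variability is
  damped to 10% inside a deceleration so the 20-bpm criterion is met with
  margin. Events keep two clear minutes from episode blocks and three from
  each other, which caps the number of stray qualifying minutes any
  6-minute window can see at four — below the persistence rule.
* **Signal loss**: a per-trace fraction (default 2-12%) planted as a few
  contiguous gaps confined to intermediate minutes away from events; the
  planted fraction is reproduced to within one sample.
* **Covariates**: gestational age 189-258 days (adverse-outcome traces
  mildly skewed later, since they are acquired within a week of a preterm
  delivery — days before delivery is drawn from 0-7), fetal sex allocated
  by exact counts (default male share 4335/8881), durations 35-75 min.
  Ten adverse-outcome subtype labels are drawn from a Gaussian copula
  (exchangeable correlation 0.3, so subtypes co-occur); any adverse-outcome
  record left unlabelled is assigned its most probable subtype, so every
  case meets at least one criterion.

### Default feature targets

| feature | NPO | APO | direction |
|---|---|---|---|
| basal FHR (bpm) | 138 | 139 | APO higher |
| accelerations | 5 | 3 | NPO higher |
| decelerations | 1 | 2 | APO higher |
| most lost beats | 12 | 15 | APO higher |
| STV (ms) | 9 | 7 | NPO higher |
| high variation (min) | 7 | 0 | NPO higher |
| low variation (min) | 0 | 5 | APO higher |

Published group medians for preterm-adverse versus normal cohorts report
deceleration medians of 0 in both groups alongside most-lost-beats medians
of 8 and 11, and episode-minute medians of 2 and 4 — combinations that the
definitional constraints above make unattainable for an extractor in which
lost beats come only from detected decelerations and episodes have a 5-minute
floor. The defaults therefore use the nearest attainable medians while
preserving every direction and the approximate magnitude of the group
differences. With 500 traces per cohort the extracted medians land within
15% of these targets (exactly 0 where the target is 0).

### What the generator does not emulate

The construction is designed for controllability, not physiological
realism. Epoch pulse intervals are piecewise constant within epochs (no
beat-to-beat noise below the epoch scale); minute ranges are pinned rather
than stochastic; accelerations are placed in intermediate-variability
minutes, whereas physiologically they cluster inside active sleep; there is
no uterine-activity channel, no fetal-movement channel, and no
gestational-age trend in the feature distributions. Because the episode
features are nearly bimodal between the two cohorts, synthetic cohorts are
*more separable* than clinical ones: the pipeline's validation AUC on
default synthetic cohorts (~0.95+) should be read as "the chain is
lossless", not as a clinical performance estimate. Passing tests
demonstrate the correctness of extraction, cohort construction, training
and evaluation machinery — not expected real-data discrimination.

## Quality control and cohort construction

`plausibility_filter()` excludes traces with >30% signal loss, basal FHR
<100 or >180 bpm, >1 acceleration per analysed minute, >125 most lost
beats, or STV <2 or >30 ms. All inequalities are strict, exactly as
printed clinically; boundary values are retained. The acceleration-rate
denominator is the analysed (<= 60 min) duration because the features are
computed on that window, and the most-lost-beats rule is likewise evaluated
after the 60-minute cap. Every exclusion is logged with its rule
identifier. `first_trace_per_week()` keeps one trace per pregnancy per
completed gestational week (the earliest); `temporal_window_filter()` drops
adverse-outcome traces acquired more than 7 days before delivery.

Propensity scores are an additive logistic model on gestational age, fetal
sex and trace duration — the minimal standard choice. Matching is greedy
nearest-neighbour on the logit score, cases processed in descending
propensity, each control used at most once, caliper 0.2 sd of the logit
score; unmatched cases are reported, and standardized mean differences are
reported pre and post. The 80:20 split and the 10 cross-validation folds
are both stratified on outcome x gestational week x 10-minute duration bin
x fetal sex (a continuous key must be discretised to stratify; 10-minute
bins keep strata populated). Largest-remainder rounding makes the global
training size exactly `round(0.8 N)`. Feature transforms are chosen by
sample skewness (|skewness| > 1: min-max to [0, 1]; otherwise z-score),
fitted on training data only, applied unchanged to validation data, and
out-of-range validation values are logged, never clipped.

## Modelling

Six families: decision tree (rpart), Gaussian naive Bayes (e1071), penalised
logistic regression (glmnet), random forest (ranger), RBF support vector
machine (e1071) and gradient-boosted trees (xgboost). Hyperparameters are
searched by a Gaussian-process expected-improvement optimiser over declared
spaces (`model_search_space()`), with a Latin-hypercube initial design, the
mean 10-fold AUC as objective, and a fixed seed making the search
deterministic; the budget (default 10-20 evaluations per family at desk
scale) is configuration. Families are compared on identical folds by
median AUC, with a Kruskal-Wallis omnibus test and pairwise two-sided
Mann-Whitney U tests at the 0.01 level. The final model is refitted on the
full training set. The SVM emits margins, not probabilities, so a logistic
link is fitted on out-of-fold decision values (probability-native families
are used as-is); decision-curve and Brier analyses need probabilities.
Random-forest feature importances are impurity improvements averaged over
trees, normalised to sum to one.

## Evaluation

AUC uses the rank (Mann-Whitney) formulation and is checked against
trapezoidal integration of the ROC curve to 1e-12. Confidence intervals
are percentile bootstrap over class-stratified resamples (B = 1000 by
default), which preserves prevalence so degenerate one-class resamples
cannot occur. Operating points: the Youden threshold (ties broken toward
the lower threshold — the higher-sensitivity side, the clinically
conservative choice), the highest threshold with >= 95% sensitivity and the
lowest with >= 95% specificity; unattainable constraints are reported as
such. Sensitivity, specificity, F1 and Cohen's kappa are reported on the
x100 scale alongside the underlying values in the JSON report. Net benefit
NB(pt) = TP/N − (FP/N) pt/(1−pt) is evaluated on thresholds 0.01-0.99
against treat-all and treat-none. Stratified AUCs are computed per
gestational week (partition) and per adverse-outcome subtype
(one-vs-all-controls, because subtypes co-occur); strata with fewer than 5
cases are flagged, and one-class strata are reported as undefined rather
than dropped. Feature association uses two-sided Mann-Whitney tests at
0.05 with Cohen's D for approximately symmetric features and rank-biserial
correlation (2 AUC − 1) otherwise — the same symmetry rule as the
transforms.

## Reproducibility and problem sizes

A single run seed fans out to per-stage seeds (`seed * 8 + offset`), so any
stage can be reproduced in isolation; the run manifest records the seed, a
configuration hash and stage-wise record counts. The test suite exercises
the pipeline at the package's chosen desk scale: 500 traces per cohort for
feature-median recovery, 200 short traces for the event-detection oracle,
and five seeds of 1000 + 1000 traces for the discrimination property; the
acceptance script runs the six-family pipeline at 500 + 500. These sizes
are the package's own trade-off between statistical resolution and a test
suite that runs in minutes.

## Known limitations

* The generator's separability overstates clinical discrimination (above).
* The baseline estimator assumes deviations are transient relative to the
  10-minute window; pathological traces dominated by very long
  decelerations would bias it. The QC basal-rate bounds catch the extreme
  cases.
* Variability inside a deceleration is damped rather than modelled; lost
  beats of overlapping events are not disentangled (the generator never
  plants overlapping events).
* Subtype labels are assigned at the record level with a single
  co-occurrence parameter; no subtype-specific feature signatures are
  planted, so per-subtype AUCs on synthetic data differ only by sampling
  noise.
* Gaussian naive Bayes has no tunable hyperparameters in this
  implementation; its "search" is the single default configuration.
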