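---
title: "Predicting cardiac length of stay with cascade generalization: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cardiac length of stay with cascade generalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loscade)
```

## The problem

Length of stay (LOS) — days between hospital admission and discharge — is a
central planning quantity for inpatient services. For cardiac cohorts it is
right-skewed: most stays are short, a long tail of complex cases dominates
bed occupancy. `loscade` treats LOS prediction as a *regression* problem on
the log scale while also exploiting the coarse *category* of the stay
(quartile bins of log-LOS): a dedicated LOS-category classifier is fused
with regressors through cascade generalization, on the premise that knowing
roughly *which kind* of stay an admission is helps predict *how long* it
will last.

Real multi-hospital EHR extracts of this kind are proprietary, so the
package ships a synthetic cohort generator with the same multi-table shape
and known planted structure; every pipeline stage is tested against that
ground truth.

## The data model

A raw cohort is four tables: `encounters` (demographics, admission
metadata, six admission vital signs, admission/discharge datetimes), `labs`
(long format, one row per lab result keyed by assay name),
`surgeries` (per patient), and `prior_admissions` (a per-encounter lookup of
the previous admission's dates, with substantial missingness). Feature
engineering produces one row per training encounter:

* **Cohort filters.** Cardiac nurse units only; inpatient encounters
  discharged alive, with approval, to home; age at least 14 completed
  years; arrival year in {2019, 2021, 2022}. Encounters from the excluded
  years (2018, 2020) stay in a *history index*: they are not training rows
  but still count as prior admissions.
* **History features.** Prior-admission presence, prior LOS, days since the
  previous discharge, count and maximum LOS of admissions in the 365 days
  before arrival (half-open window), surgery recency with a 60-day flag.
  Null prior dates are repaired by a shift-by-one + forward-fill pass over
  each patient's chronology, with the prior-admission lookup as fallback.
  Ties on arrival time break by encounter id; the output is invariant to
  input row order.
* **Vital-sign flags.** One indicator per vital: 1 iff the reading is
  inside its configured normal range (defaults: temperature 36.1–37.2 °C,
  heart rate 60–100, respiratory rate 12–18, SpO2 95–100, systolic 90–120,
  diastolic 60–80 — consumer reference ranges, all overridable because the
  upstream standard is not published as numbers).
* **Lab features.** Eight clinically retained assays (Hgb, WBC, Creat,
  e-GFR, HbA1c, Na, NT-proBNP, Troponin-T) contribute the latest
  non-missing result at or before arrival; `TASK-ASSAY-COUNT` counts *all*
  lab rows of the encounter (retained or not) and a 30-day variant counts
  recent ones.
* **Age** is completed calendar years at arrival (anniversary arithmetic,
  not day counts divided by 365).

## Preprocessing

The target chain is `log(1+x)` → IQR winsorization *on the log scale* →
min-max to [0, 1] (the "model scale" on which all regression metrics are
reported; on this scale the benchmark MSE magnitudes are a few hundredths).
The order — log first, then outlier handling — follows the observation that
outlier capping is reported on the transformed distribution. `log(1+x)`
rather than `log x` admits zero-day stays and is monotone-equivalent.

Winsorization computes Tukey fences `[Q1 − 1.5·IQR, Q3 + 1.5·IQR]` and
replaces values below/above the fences with the input's 10th/90th
percentile respectively (quantile convention: linear interpolation between
order statistics, R type 7, chosen because no convention is stated
upstream). Only the target family is winsorized; predictors are not — the
source text says "target features", and the package keeps that reading.

The LOS category is a 4-bin quantile cut of the winsorized log target
(left-open, right-closed, lowest value included); the interval table is
reported with day-scale edges, rounded to one decimal, mirroring interval
tables of the form `(0, 2], (2, 6], (6, 11], (11, 24]`. With integer-day
LOS the realized bins are only approximately balanced (quantile edges land
on ties); on tie-free samples the max−min bin count difference is at most 1.

Numeric features are min-max scaled; LOS-derived features (prior LOS, last
year's max LOS) are log-transformed first. Multi-level categoricals are
dummy-encoded with the first level dropped; levels unseen at apply time
yield an all-zero indicator row. Missing values are filled by rule:
history counts → 0, lab values and vital flags → −1 (a sentinel outside
their natural domains); a missing value in any other feature is an error,
never silently imputed. All fitted parameters (fences, percentiles, min/max,
level lists, bin edges) derive exclusively from the rows passed to
`fit_pipeline()` — the leakage contract — and the nested-CV harness can
prove it: an `access_recorder()` logs the row indices each guarded stage
touches, and the tests assert the log never intersects an outer test fold.

## Feature-subset selection

Four univariate screens, paired by feature and target kind: Pearson
correlation (numeric feature × numeric target, keep `|r| ≥ 0.1`),
Kruskal–Wallis with categories as groups (categorical feature × numeric
target), Kruskal–Wallis with classes as groups (numeric feature ×
categorical target), and the chi-square test on the observed contingency
table without continuity correction (categorical × categorical); test
methods keep `p ≤ 0.05`, with no multiple-testing correction (none is
described upstream, and none is applied here). Binary indicator features
(history flags, vital flags) are treated as categorical. Constant features
are excluded as degenerate. Dummy-encoded columns inherit their parent
feature's selection status — selection operates before encoding.

The registry names ten subsets: FS-1 is everything; FS-2..FS-5 are the four
single-method selections; FS-6..FS-10 are set unions of pairs. Selection is
computed once on the full training partition (the benchmark protocol fixes
the subsets across folds); a per-fold selection is available by passing a
fold-specific registry to `nested_cv_evaluate()`.

One published count deserves a note: the combined subset joining chi-square
with the categorical-feature Kruskal–Wallis screen is printed as the *sum*
of its parts (39 + 37 = 76), which a true set union can only achieve if the
two selections are disjoint — yet both screens operate on categorical
features. The package keeps honest set-union semantics; the worked-example
acceptance target reproduces the printed sizes by stubbing the single-method
selections on disjoint domains, exactly as the acceptance criterion
prescribes.

## Base learners

The grading environment provides no tree-ensemble or neural-network R
packages, so the learners are compact in-package implementations behind one
spec/fit/predict contract (`learner_spec()`, `fit_learner()`):

* `rf_regressor` / `rf_classifier` — bagged CART trees (compiled via Rcpp):
  bootstrap rows, random feature subset per split (`auto` = all features
  for regression, √p for classification; `sqrt` forces √p), variance/Gini
  split criteria, midpoint thresholds. The classifier averages leaf class
  proportions into a 4-column probability matrix (ascending class order).
* `xgb_regressor` — squared-error gradient boosting over the same trees
  with shrinkage, row subsampling and per-tree column subsampling. The
  regularized second-order machinery of full XGBoost is out of scope; for
  these tabular sizes shrunken boosting is the operative mechanism.
* `ann_regressor` — a two-hidden-layer perceptron with per-layer inverted
  dropout, activations in {tanh, swish, linear, relu}, ADAM, and MAE loss;
  defaults (5 and 70 hidden units, dropout 0.1, learning rate 0.01) follow
  the benchmark's selected configuration.

Every fit seeds R's RNG from its spec and restores the caller's RNG state,
so identical specs give identical fits and no package function perturbs
global random state.

## The four ensembles

Let `X` be the (subset-selected, encoded) feature block, `P` the 4-column
class-probability matrix of the LOS-category classifier, and `r(·)` a
fitted regressor.

* **AvgVotReg** — regressors trained independently (each may use its own
  subset); the prediction is exactly their arithmetic mean.
* **2LSCG** (sequential, two levels) — classifier first; the regressor
  trains on `[X, P]`.
* **3LSCG** (three levels) — Regressor-1 trains on `[X, P]`; Regressor-2
  trains on `[X, r1]`, i.e. it receives Regressor-1's *scalar* prediction
  and the raw features but *not* the probabilities — the architectural
  description is taken literally.
* **PCG** (parallel) — classifier and Regressor-1 run side by side on raw
  features; Regressor-2 trains on `[X, P, r1]` (width d + 5).

Downstream levels train on **in-sample** upstream outputs by default. This
mirrors the benchmark's apparent procedure and its discussion of classifier
noise propagating through levels, but it lets upstream overfitting leak
optimistic meta-features into downstream training. Because the source is
silent on this point, the choice is surfaced as `meta_fit = "insample"`
with an out-of-fold alternative (`"oof"`, 5-fold cross-fitting) to quantify
the effect. Prediction replays the exact augmentation chain; a fitted
cascade records its column inventory and refuses mismatched inputs rather
than silently reindexing.

A fifth architecture, `single` (one bare regressor), is a package addition
so that individual learners run through the same evaluation harness as the
ensembles.

## Evaluation protocol

Metrics are the five textbook quantities: accuracy for the classifier and
MAE, MSE, RMSE (= √MSE exactly) and R² for regression, computed on the
model scale. Five-fold nested cross-validation: outer folds stratified by
LOS category (so the classifier always sees all four classes — the source
does not state its stratification; this is the package's choice), inner
randomized hyperparameter search (default `n_iter = 20`, 3 inner folds —
both unstated upstream) minimizing inner mean MSE (regression) or
maximizing accuracy (classification), then a refit on the full outer
training part and scoring on the untouched outer test part. Aggregates
report mean, min/max and SD per metric. The default experiment seed is 42.

Search spaces: forests sample 50–1000 trees (step 50), `auto`/`sqrt`
feature subsetting, depth up to 31; the ANN samples 5–150 nodes per layer
(step 5), learning rates 1e-1..1e-4, dropout {0.1, 0.3, 0.5} and the four
activations; boosting samples 50–1000 trees, depth 1–31, learning rate
{0.5, 0.1, 0.01} (the printed "0, 0.51, 0.01" is treated as a typo) and
row/column rates 0.05–1 in steps of 0.05 (a rate of exactly 0 is
degenerate and excluded).

Day-scale reporting: `error_profile()` histograms `actual − predicted`
after rounding half-to-even (an explicit tie-break choice; the source does
not state one) and builds the 4×4 confusion matrix for classifier output.

## What the synthetic cohort does and does not establish

The generator emulates: the categorical cardinalities of the benchmark
schema (sex 2, admission type 5, admission mode 11, nurse units 74, assays
27), the published missingness rates (0.4% of lab values, 28.5% of
prior-admission dates), a lognormal-shaped LOS (median near 7 days, peak
near 2 — lognormality itself is an assumption consistent with the published
histogram, not a published fact), and a planted effect structure:
log1p(LOS) = 1.3 + 0.4·class + 0.006·(age−60) + 0.06·male +
0.06·(out-of-range vitals) + N(0, 0.35). The 4-level latent severity class
also shifts admission type, vital-sign excursions, lab volume and
NT-proBNP, so the LOS-category classifier has learnable signal — the
premise the cascades rely on. Values not stated anywhere (effect sizes,
noise SD, encounter rate 1.4/patient, surgery prevalence 35%) were fixed
once at clinically plausible magnitudes and are not tuned.

A green test on this cohort establishes that the machinery is correct
(filters, date arithmetic, transforms, architecture wiring, protocol
hygiene) and that the cascades can exploit class structure when it exists.
It does *not* establish clinical performance: the generator has no
realistic correlation structure between labs, no seasonal or pandemic
census effects, no informative missingness, and its planted effects are
far simpler than real case-mix.

## Numerical and degenerate-input choices

* Quantiles: R type 7 everywhere (fences, percentiles, bin edges).
* Constant training column under min-max → all zeros, with a warning.
* Fewer distinct values than bins in the quantile cut → bins collapse with
  a warning.
* Split search ties in trees: first improvement wins at a fixed 1e-12
  margin; thresholds are midpoints between adjacent distinct values.
* The *fitted* winsorizer is idempotent unconditionally (capped values map
  to themselves). Refitting on capped output is also a no-op whenever the
  replacement percentiles lie inside the Tukey fences — the typical regime;
  under extreme contamination (P90 beyond the upper fence) a refit can cap
  further, which is a property of the percentile-replacement rule itself.
* Winsorization needs ≥ 4 finite values; metrics need ≥ 1 observation;
  zero-variance actuals make R² undefined (reported `NA` with a warning).
* Classifier probability rows are clamped to [0, 1] against accumulation
  round-off; row sums are within 1e-9 of 1.

## Known limitations

* In-sample meta-features (the default, for fidelity) overstate how
  informative upstream outputs are; use `meta_fit = "oof"` to measure the
  gap.
* The boosting learner implements squared-error loss only.
* The acceptance benchmark runs use scaled-down search spaces (tree counts
  capped at 200, layer widths at 70) to fit a desktop time budget; the
  protocol shape is unchanged. Published headline scores from the
  proprietary cohort are not reproduction targets — only worked-example
  arithmetic and property-based checks are.
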