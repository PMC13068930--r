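---
title: "Methods: brain-age gap modelling and exposome-based prediction of grey-matter health"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: brain-age gap modelling and exposome-based prediction of grey-matter health}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`expobag` implements a two-stage analysis of structural brain health in an
aging population:

1. **Normative brain-age modelling.** Regression models predict
   chronological age from parcellated grey-matter volumes in a healthy
   reference sample. After a training-set age-bias correction, the *Brain
   Age Gap* (BAG) — adjusted predicted age minus chronological age — serves
   as a per-participant indicator of grey-matter health: positive values
   mean an older-appearing brain.
2. **Exposome-wide prediction of BAG.** A curated table of exposure
   variables (biomedical, lifestyle, socio-affective, early-life,
   environmental, socio-economic) predicts BAG under leakage-safe repeated
   nested cross-validation, with permutation significance, FDR control
   across metrics, and Shapley additive explanations of the fitted models.

Both stages are exercised on a synthetic cohort generator with planted,
exported ground truth, so every contract — bias-correction identities,
leakage guarantees, attribution recovery — can be tested without any
restricted data.

# Stage 1: brain age and the bias correction

## Candidate models and selection

Four algorithms (linear regression, ridge regression, support vector
regression, random forest) can each be trained on grey-matter
representations at several granularity levels. For each candidate the
healthy sample is split 80/20, stratified by age decile (the stratification
variable is a design choice recorded here; the split fraction is
configurable). On the training fraction, hyperparameters are tuned by an
inner cross-validation loop, a repeated outer loop provides fold-wise error
estimates and out-of-fold predictions, and the tuned model is evaluated
once on the untouched held-out rows. The candidate with minimal held-out
MAE wins; ties are broken by higher held-out Pearson r, then by
lexicographic candidate name, so selection is deterministic. The winner is
refitted on the full healthy sample before being applied to new
participants. Features are standardized with training-fold statistics at
every level of the hierarchy — the tuning loop sees the same standardized
representation that the final fit uses, which matters because the ridge
penalty is scale-dependent.

## Age-bias correction

Brain-age predictions are systematically shrunk toward the training mean:
young participants are over-predicted and old ones under-predicted, which
induces an artefactual negative correlation between the raw gap and age.
The correction fits ordinary least squares of predicted age on
chronological age **in training data only** (slope \(a\), intercept
\(b\)), then inverts the line:

\[ \widehat{\mathrm{age}}_{\mathrm{adj}} = (\widehat{\mathrm{age}} - b)/a,
   \qquad \mathrm{BAG} = \widehat{\mathrm{age}}_{\mathrm{adj}} - \mathrm{age}. \]

Two identities follow analytically from OLS on the fitting set and are
asserted to tight numerical tolerance in the tests: the mean BAG is zero,
and BAG is uncorrelated with age. On held-out data the correction strictly
shrinks the |BAG–age| correlation whenever the model exhibits
regression-to-the-mean bias. A guard rejects |slope| below `1e-6` (a
prediction carrying no age signal cannot be inverted); the tolerance
protects the division and is deliberately far below any plausible real
slope.

In the pipeline the correction is estimated from the *out-of-fold*
training-set predictions of the selected model rather than its in-sample
predictions. In-sample predictions of flexible learners are optimistically
compressed (a random forest nearly memorizes its training rows), which
would understate the slope actually seen on new data; out-of-fold
predictions estimate the deployment-time relation between prediction and
age while still using training data only.

# Stage 2: exposome curation and prediction

## Curation rules

The curation chain applies, in order: record uniqueness (duplicate rows per
participant removed, first occurrence kept, conflicting cells logged —
keep-first is a documented decision, the audit trail records every
conflict); aberrant-value exclusion (cells outside a variable's valid range
or category set are nulled); uninformative-value exclusion (configured
"do not know"/"prefer not to answer" codes nulled); duration derivation
(for each onset-age variable, duration = assessment age − onset age;
onsets after the assessment are inconsistent and yield missing values,
logged); and minimum-availability filtering (variables observed in fewer
than `n_min` participants, or in a single sex, are dropped; the boundary is
inclusive). No step imputes anything — the non-missing cell count is
non-increasing through the chain except for the new duration columns — and
the chain is idempotent. The audit report reconciles exactly with
cell-level differences.

The reference availability threshold of 2000 participants is defined
against a population of roughly 34k; for synthetic cohorts the default
scales that ratio to the simulated population size (configurable).
Ordinal and categorical variables are kept as ordinal-coded integers and
standardized downstream rather than one-hot expanded, so each variable
receives a single attribution value. Pairwise-complete correlations are
used for the redundancy matrix because block missingness makes listwise
deletion empty.

## Leakage-safe nested cross-validation

`run_prediction()` uses `outer_repeats × outer_folds` outer splits with
`inner_folds` tuning folds. Within every outer fold, in order:
feature standardization (training-fold means/SDs), confound
residualization (per-variable OLS on age, age², sex, height and volumetric
scaling with an intercept, coefficients fitted on training rows only), and
hyperparameter tuning on inner folds of the training fold. Every artifact
— scaler, confound coefficients, tuned hyperparameters — is a pure
function of training-fold rows; the test suite verifies this by tampering
with test-fold rows and asserting byte-identical artifacts. Inner tuning
reuses the outer-training-fold standardization rather than re-deriving it
per inner fold; this touches training data only and keeps the inner loop
affordable. Sex is a covariate by default and can instead be moved into
the predictors (`sex_as_predictor`). Fold assignment can be keyed on
sorted row identifiers, making all results invariant to the row order of
the input table.

Metrics per test fold: MAE, MSE, RMSE, coefficient of determination
\(R^2 = 1 - SS_{res}/SS_{tot}\) (which can be negative on test data —
deliberately not the squared correlation), and Pearson r. The primary
summary is the fold-wise mean; pooled-per-repeat r is also reported
because the two aggregations are not identical at small fold sizes.

## Permutation significance and FDR

The null distribution shuffles the target and re-runs the outer
cross-validation. Because the feature pipeline (standardization,
residualization) does not depend on the target, the per-fold processed
matrices are cached and each permutation only refits the learner — this
"fast mode" reuses the tuned hyperparameters; full re-tuning inside every
permutation is available (`retune = TRUE`) at proportional cost. The
p-value is \((1 + b)/(1 + B)\), where \(b\) counts permutations at least
as good as the observed value — "at least as good" means ≥ for r-type
metrics and ≤ for error metrics. The smallest attainable p is therefore
\(1/(B+1)\): about 0.002 at the default \(B = 500\). Calibration is
verified empirically: with a target independent of the features the
p-values are uniform. P-values across the five metrics are adjusted with
the Benjamini–Hochberg step-up (via `stats::p.adjust`); the test suite
checks it against a brute-force step-up oracle.

## Shapley attributions

`compute_attributions()` produces additive per-sample, per-variable
contributions satisfying local accuracy: base value + row sum of
attributions = model prediction, checked for every explained sample
(default tolerance `1e-6` × the prediction SD; violations are an error,
not a warning). Three estimators:

* **Tree ensembles** — the exact path-dependent polynomial-time tree
  algorithm, implemented in C++ (`src/treeshap.cpp`), with node covers
  counted from the training-fold background. The implementation is tested
  against a brute-force subset-enumeration Shapley oracle on small trees.
* **Linear/ridge** — the closed form \(\phi_j = \beta_j (x_j - \bar x_j)\)
  with background means.
* **Anything else** — a permutation-sampling estimator: for each sampled
  feature ordering, features switch from background to observed values one
  at a time and the change in mean prediction is credited to the switched
  feature. Each ordering's contributions telescope exactly to
  \(f(x) - \mathbb{E}_b f(b)\), so local accuracy is exact at any budget;
  the budget only controls the variance of the per-feature split.

Attributions are computed on held-out folds only, with the fold's own
model and background, and concatenated across folds; the reported ranking
uses mean |attribution| with name tie-breaks. Stability across folds is
the mean pairwise Spearman correlation of per-fold mean-|attribution|
profiles (the choice of Spearman is a design decision; the underlying
quantity is a ranking). Directionality is summarized as the correlation
between a variable's value and its attribution (`sign_assoc`), not as a
regression effect size — multivariate attributions are not regression
coefficients, which is also why the package provides the traditional
per-variable confound-adjusted standardized betas
(`univariate_association()`) as a separate, complementary view. The
contrast between the two views is exactly what identifies *moderator*
variables: near-zero marginal association, high multivariate contribution.

# The synthetic cohort generator

## What it emulates

Participants get an age uniform on a configurable range (default 44–82
years), sex, sex-dependent height, and a volumetric scaling factor. Each
participant carries an *aging deviation* \(d\) (years): the sum of planted
exposure contributions plus Gaussian noise. Regional grey-matter volumes
decline linearly with the *effective brain age* \(\mathrm{age} + d\), with
per-region intercepts, slopes, sex offsets, height and scaling
coefficients, plus i.i.d. Gaussian noise; coarser granularity levels are
grouped means of consecutive fine regions. Exposome variables are drawn
independently (normal, lognormal, ordinal, binary) and contribute to
\(d\) per their effect kind:

* linear: `strength × z(x)`;
* nonlinear: `strength × (z(x)² − 1)/√2` (standardized quadratic, zero
  mean, unit variance);
* duration: the table carries only an *onset age* column — the analysis
  must derive the duration itself — and `strength × z(duration)` enters d;
* moderator / interaction: `strength × z(x) × z(partner)`. The product of
  independent standardized variables has zero mean and zero covariance
  with each factor, so a moderator is marginally uncorrelated with \(d\)
  **by construction** — this reproduces, at the level where it is
  testable, the phenomenon of a variable that predicts brain health only
  in interaction with others;
* null: nothing.

Health-eligibility flags mimic selection of a healthy reference norm: the
top configurable quantile of |d| is flagged as failing at least one
criterion (long-standing illness, diabetes, stroke, diagnosis, self-rated
health), so the healthy sample under-represents large deviations.
A configurable fraction of participants (default one half) forms the
population set for the exposome analysis; the remainder is the
model-building pool. The two sets are disjoint by construction and the
pipeline enforces it. Block-structured missingness (variable set ×
participant fraction) reproduces main/replication/variables-restricted
style subsets; designated variables also emit uninformative codes (−1/−3)
and occasional out-of-range values so the curation rules are exercised on
realistic dirt.

A single integer seed expands into per-component substreams (demographics,
exposome, deviation noise, region parameters, region noise, flags,
missingness, split) through a fixed multiplicative recurrence
(`substream_seed()`), so the whole bundle is byte-reproducible and each
table is independently reproducible.

## Default study conditions and why

The desk-scale defaults are 3000 participants, 100 fine regions with
granularity levels 100/50/25, and 60 exposome variables: 10 effect
variables (six linear with strengths 2.5/2.0/1.75/1.5/1.25/1.25 years per
SD, two nonlinear at 1.75/1.5, one duration-type at 1.75, one moderator at
2.5 paired with the strongest linear exposure) plus 50 null variables
across distribution families. Residual deviation noise has SD 2 years.
Grey-matter noise of 20 volume units per region against aging slopes near
1 unit/year yields a brain-age model with held-out MAE between 3.5 and 4
years — the accuracy regime reported for well-tuned grey-matter models on
real cohort data. The planted-effect scale is chosen so that each effect
is individually *small* relative to the outcome (the weakest explains
about 3% of BAG variance, the strongest about 12%) yet detectable against
the 50 null variables at the default cohort size — deviations from a
healthy norm must be recoverable for recovery experiments to be
informative, while single-exposure effects stay modest, matching the
field's consistent finding that brain health reflects many small
contributions rather than a few large ones.

## What it does not emulate

Independent draws ignore the correlation structure of real exposome
tables (real redundancy is low but not zero); there is no atlas topology,
no spatial correlation between regions beyond the shared effective age,
no longitudinal visits, no family relatedness, and exposure effects are
constant in time rather than lagged. Passing tests therefore demonstrate
the statistical machinery — leakage discipline, calibration, recovery of
planted structure — not performance claims about any real cohort.

# Numerical choices and degenerate inputs

* Ridge penalties on a log grid (`1e-3`–`1e3`); compact SVR and
  forest grids sized for single-CPU runtimes. Grids are configurable per
  call.
* Standardization guards zero-variance features (SD set to 1; the
  residualization then removes the constant).
* `fit_bias_correction` requires ≥ 3 pairs, non-degenerate age variance,
  |slope| ≥ 1e-6.
* Degenerate targets (constant y, fewer than two distinct ages) are
  errors, not silent NAs.
* Ties in model selection and attribution ranking are broken
  lexicographically for determinism.
* Zero-variance variables in the redundancy matrix yield NA entries and
  are reported, not dropped silently.

# Problem sizes used by the test-suite experiments

The repeated simulation experiments run at reduced but statistically
adequate sizes chosen by the package: the planted-effect recovery study
uses ten cohorts of 3000 participants with the default conditions above, a
5-fold × 1-repeat outer loop, 40-tree depth-capped forests (depth 7,
mtry 12 — deep enough to express the planted interaction and quadratic
terms while keeping 99-permutation nulls affordable) and 99 permutations;
the
permutation-calibration study uses 200 replicate null datasets with 99
permutations of a fixed-penalty ridge pipeline; bias-correction properties
use ten cohorts of a few hundred participants. The acceptance script runs
the full pipeline once at the default conditions with 500 permutations,
mirroring the default significance procedure.

# Known limitations

BAG is a derived indicator: its variance mixes true deviation with model
error, and the attribution analysis inherits that attenuation. The
moderator construction produces exact marginal orthogonality only in
population; finite samples show small non-zero correlations. Fast-mode
permutations condition on the tuned hyperparameters; when tuning is highly
variable, full re-tuning gives a slightly wider null. The sampling
attribution estimator is exact in its sum but its per-feature split is
Monte Carlo; tree and linear estimators are exact throughout.
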