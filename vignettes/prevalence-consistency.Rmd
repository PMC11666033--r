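---
title: "Measuring the prevalence-consistency of binary classification metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the prevalence-consistency of binary classification metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

A model's evaluation should measure the model, not the dataset it happened
to be evaluated on. Yet most confusion-matrix metrics depend on the
prevalence φ of the positive class: re-evaluating the same model on data
collected in a different period, site or population can change its score —
and its rank among competing models — purely because φ changed.
`prevmetrics` operationalizes this concern: it holds the sample size and the
relationships among variables (approximately) fixed, walks prevalence across
nearly its whole range, and measures each metric's *consistency* as the
variance of its values and of its model rankings across that walk.

## The metric algebra

Everything single-threshold starts from the four counts TP, FN, TN, FP. The
catalogue (`metric_catalogue()`) implements 18 study metrics plus the raw
counts and complement rates, each in two forms:

* **count form** (`metric_from_confusion()`), the textbook formulas; and
* **rate form** (`metric_from_rates()`) in the quadruple (n, φ, TPR, TNR),
  which exposes each metric's prevalence dependence analytically — e.g.
  accuracy = TPR·φ + TNR·(1−φ) is a convex combination of the two rates, and
  F1 = 2·TPR·φ / (2·TPR·φ + (1−TNR)(1−φ) + (1−TPR)·φ) is strictly
  increasing in φ at fixed rates, which is why F-scores track prevalence.

The two forms agree to 10⁻¹⁰ on random confusion matrices (a property the
test suite enforces), so the rate form is a derivation, not a second
definition. Two algebraic choices deserve note:

* **Cohen's kappa** uses the expected accuracy
  φ²·TPR + φ(1−φ)(2−TPR−TNR) + (1−φ)²·TNR, the n²-normalized form of
  ((TP+FN)(TP+FP) + (TN+FP)(TN+FN))/n². This is the form that reproduces
  the published evaluation table; a variant with an extra 1/n factor that
  sometimes appears in print does not.
* **Weighted F-scores** implement the standard
  (1+β²)·PPV·TPR / (β²·PPV + TPR) with β ∈ {0.5, 2} by default. The
  published weighted F-score rows for the recidivism models are *not*
  reproducible from this formula applied to the published counts (the
  formula behind them is not identifiable), so `toy_fixtures()` tags them
  `known_discrepant` and tests assert the discrepancy rather than the
  values.

**Undefined cells.** PPV, NPV, DOR, MCC, FM and friends have exact zero
denominators at extreme thresholds or degenerate matrices. The package
returns a tagged `NA` (`undefined_reason` says which denominator vanished)
instead of `Inf`/`NaN`; every aggregation skips such cells and reports how
many were skipped. This matters in the threshold analysis, where thresholds
near 0 and 1 routinely empty the predicted-positive or predicted-negative
margin.

**AUC** is deliberately not a confusion-matrix metric here: `auc_rank()`
computes the normalized Mann–Whitney statistic from average ranks (ties
credited ½), which equals the trapezoidal area under `roc_points()` to
10⁻¹², and is invariant under strictly increasing score transforms.
Requesting AUC from a single confusion matrix is an error by design.

**Thresholding rule.** A case is called positive when score ≥ t. The
convention makes t = 0 the all-positive endpoint and calls a score of
exactly 0.5 positive at the default cutoff; the strict rule is available via
`rule = "gt"` everywhere thresholds are applied.

**Comparisons with published values** round half-up at the printed precision
(`round_half_up()`), only in tests — never inside computations.

## The prevalence sweep

`run_sweep()` starts from a dataset with n rows and repeatedly swaps k cases
between classes: each downward step removes k uniformly sampled positives
(without replacement) and adds k negatives sampled with replacement; upward
steps mirror this. Both arms chain cumulatively from the original data, so
the class counts follow the exact schedule pos₀ ± k·i independent of the
random draws — with the default k = 30, 76 downward and 79 upward
iterations from (2775, 3439), the endpoints are (495, 5719) and
(5145, 1069) and the series has 156 datasets spanning φ ≈ 0.08–0.83.

Added cases are drawn from the *original* class pool by default
(`pool = "original"`): resampling from the evolving dataset would let early
duplicates breed further duplicates, and drawing from the original pool
keeps the duplication process stationary. Both modes are implemented; the
class-count schedule is identical either way.

The design goal — prevalence moves, relationships don't — is verifiable:
`correlation_drift()` numerically encodes all columns, compares each
dataset's correlation matrix entrywise against the original's, and reports
the maximum absolute deviation (constant columns are excluded and counted).
On the synthetic default the median drift sits well below 0.1.

Iteration counts are fixed by configuration, mirroring a design where the
arms end when the reference model's TPR (downward) or TNR (upward)
saturates; an optional `saturation_eps` reproduces that stopping rule with a
logistic-regression probe, but it is off by default because fixed counts
keep the schedule exactly reproducible.

## Models and the baseline

Five families sit behind `fit_predict()`: logistic regression (`stats::glm`),
random forest (`ranger`), k-nearest neighbours (`class::knn`), linear
discriminant analysis (`MASS::lda`) and gradient-boosted trees (`xgboost`).
Hyperparameter grids are deliberately small — RF trees {100, 300}, k ∈
{5, 15, 31}, GBM depth {1, 3} at learning rate 0.1 — because the study's
claims concern metric behaviour, not tuning; selection is by mean validation
AUC over stratified 10-fold cross-validation (a singleton grid skips the
loop). Categorical features are one-hot encoded with training-set levels;
features are standardized by training mean/sd for the distance- and
projection-based families (k-NN, LDA). All fits are single-threaded and
seeded, so identical seeds give identical scores.

The baseline, `random_guess()`, assigns exactly round(φ·n) positive calls
uniformly at random at the realized test-set prevalence φ, with scores
uniform on [0.51, 0.99] for positive calls and [0.01, 0.49] otherwise. Its
accuracy concentrates at φ² + (1−φ)², and its chance-corrected metrics
(BI, kappa, MCC) center on zero — both enforced as tests.

## Consistency: ranks, variances, and the group tests

`evaluate_grid()` fills the (dataset × model × metric) grid: each dataset is
split 80/20 (4971/1243 rows at n = 6214), models are fit on the training
part, and all single-threshold metrics are computed at t = 0.5 on the test
part while AUC uses all thresholds. Prevalence is reported for the test
split, which is what the metric values refer to; with random splitting it
tracks the full-dataset prevalence closely.

`rank_models()` ranks the models per (dataset, metric) with rank 1 best
under the metric's catalogued orientation, ties replaced by their average
(so rows always sum to m(m+1)/2) and undefined cells ranked jointly last.
`ranking_variance()` then takes the sample (n−1) variance of values and of
ranks across datasets — variance *with respect to prevalence*, the study's
consistency measure.

`variance_equality_tests()` compares the prevalence-sensitive group (the
three F-scores, Jaccard, TNR, TPR, Fowlkes–Mallows) against the remaining
metrics; the insensitive group is defined by complement, and both sets are
overridable. Values are first centered within each (metric, model) cell so
that dispersion measures variation across prevalence rather than
differences in metric location; the F-test compares the two pooled groups,
Bartlett and Levene use the group-by-model interaction as their grouping
factor. One caveat is baked into the tests' interpretation: on raw values
the unbounded DOR dominates its group's pooled variance, so the *direction*
of the pooled ratio is only meaningful on the scale-free ranks; the
significance of the difference is what the tests assert.

## The all-thresholds analysis

`threshold_sequence()` orders thresholds by distance from 0.5 (0.5 first,
distance ties toward the smaller threshold); the default thresholds are the
distinct predicted scores of each test set — above 1200 of them for a
1243-row test set under models with continuous scores — with a uniform grid
as fallback for score-coarse models like k-NN. `metric_threshold_grid()`
evaluates every metric at every threshold (AUC constant by construction);
`incremental_average()` averages each metric over growing threshold
prefixes per dataset — skipping undefined cells rather than imputing, since
PPV/NPV/DOR explode near the endpoints — and takes the variance of those
averages across datasets; prefix sizes run to the smallest threshold count
among a pair's datasets so every variance covers all datasets.
`ols_slope()` regresses that variance on the number of thresholds. An
exactly constant curve (AUC) is reported as slope 0 with p = 1 rather than
an ill-posed exact-fit regression.

## The synthetic generator

`generate_dataset()` emulates a recidivism-style tabular problem: n = 6214,
target prevalence 0.452, and seven features — gender ~ Bernoulli(0.8), age
~ Normal(34, 12) truncated at 18, three criminal-history counts as
zero-inflated Poissons (history counts are zero-heavy in such data), a
binary crime degree and a five-level charge category. The outcome is
Bernoulli with logistic mean; `calibrate_intercept()` solves for the
intercept on a large fixed-seed feature sample (root-finding to 10⁻¹⁰, well
inside the 0.005 calibration tolerance), so the realized prevalence lands
within binomial noise of the target at any seed. The default coefficients
are a documented tuning choice, not an estimate: they place fitted
logistic-regression test AUC at ≈ 0.71 (0.69–0.73 across seeds), the regime
observed for real recidivism classifiers, which also yields the
characteristic TPR/TNR crossing near φ = 0.5 along the sweep.

What the generator does *not* emulate: dependence among the features (they
are drawn independently, whereas real criminal-history variables correlate),
heavy-tailed count distributions, and any real-world meaning of the charge
levels. Tests passing on this synthetic study therefore demonstrate that
the *pipeline and the metric behaviour* reproduce the expected patterns
under a faithful data-generating mechanism — not that any specific published
variance value recurs, which would require the original data and trained
models.

## Problem sizes in the shipped tests

The acceptance-level synthetic study in the test suite covers the same
prevalence span (~0.09–0.84) with 32 datasets (k = 150, 15 downward and 16
upward iterations) instead of 156, singleton hyperparameter grids, and the
full 18-metric × 6-model grid — the smallest design we found that
reproduces the qualitative findings stably: AUC attains the smallest mean
ranking variance, all three variance-homogeneity tests reject at 0.05 for
values and ranks, a strict majority of variance-vs-thresholds slopes is
significantly negative, and AUC's slopes are zero to floating-point noise.
Exact desk-scale checks (the worked MCC examples, the published evaluation
table, the sweep's class-count schedule) run at their original sizes.

## Known limitations

* The published weighted F-score rows cannot be validated (see above); the
  two AUC rows of the published table require score vectors that were never
  printed, so they are carried as reference values only.
* Up-sampling duplicates rows; extreme sweep iterations contain many
  duplicated minority-class cases, which slightly flatters models with high
  capacity (they partially memorize duplicated points shared between train
  and test splits). This is inherent to the constant-n swap design.
* Bartlett's test assumes normality within groups; for ranks it is used as
  a descriptive companion to Levene's more robust test.
* The pipeline is binary-only; multi-class extensions (one-vs-rest or
  one-vs-one binarization) are out of scope.
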