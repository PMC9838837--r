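---
title: "Survey weights in gradient boosting: the svyboost simulation framework"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Survey weights in gradient boosting: the svyboost simulation framework}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Population-based surveys select participants with unequal probabilities —
over-sampling hard-to-reach demographic groups is routine — and publish a
sampling weight per participant so that weighted sample statistics estimate
population quantities. Most machine-learning toolchains either ignore such
weights or handle them inconsistently. `svyboost` studies the consequence
for gradient-boosted classification: how far does a weight-naive model's
apparent performance drift from its performance in the target population,
and how much of that drift can be repaired after the fact by rescoring the
naive model against weighted outcomes?

The package answers this by simulation. It owns four pieces: a synthetic
complex-survey generator, survey-weighted classification metrics with
bootstrap intervals, a weighted/unweighted xgboost configuration engine,
and a three-scenario evaluation framework, all orchestrated by a seeded
grid runner.

## The generative model

`baseline_population(seed)` defines a population with 27 predictors whose
mix mirrors a mortality-prediction case study: four continuous variables
(age-, BMI- and two blood-pressure-like, standard normal within stratum)
and 23 categorical variables with 2–5 levels (sociodemographics, health
behaviours, clinical history items). The binary outcome follows a joint
logistic model,

$$\Pr(y_i = 1 \mid x_i) = \operatorname{expit}\!\big(\beta_0 + x_i^\top \beta \cdot s\big),$$

where $s$ is a global coefficient-scale factor (1 at baseline). The
per-predictor coefficients stand in for unpublished marginal fits from the
original survey and are drawn once per seed: continuous coefficients from
Uniform(0.2, 0.8) on the standardized scale and categorical coefficients
from Uniform(−0.7, 0.7). These ranges were chosen so the baseline model's
F1 sits between the weak (≈0.6) and strong (≈0.85) predictor regimes, which
keeps both the doubling and the halving modification informative. Each
categorical predictor contributes through a single coefficient applied to a
centred, unit-variance numeric level score rather than through one-hot
level effects; this keeps exactly one coefficient per predictor column, so
"zeroing a predictor" is unambiguous, at the cost of imposing an ordinal
effect structure on nominal categories. The boosting engine itself sees raw
integer level codes and is free to split them arbitrarily.

The intercept $\beta_0$ is calibrated by Monte Carlo (20,000 frame draws,
seeded from the spec seed, root-solved with `uniroot`) so the *population*
prevalence matches the case study's 6,137/15,820 ≈ 0.39. Because sampling
favours the low-outcome strata, the *sample* prevalence comes out near
0.28–0.30, and this gap between sample and population outcome distributions
is precisely what separates the analytic scenarios.

### Strata and informative weights

Four design strata have frame shares of ¼ each and selection probabilities
(0.9, 0.5, 0.2, 0.05) — the rarely selected strata emulate targeted
over-sampling designs in reverse and receive the largest weights.
Continuous predictor means shift by (−0.4, 0, 0.4, 1.0) across strata, and
categorical level probabilities are tilted by the same shifts at half
strength, so stratum membership is (imperfectly) recoverable from
covariates: the mechanism that lets a flexible learner "post-stratify"
without seeing the weights.

`simulate_weights(n, mean, sd, rank_driver, seed)` draws log-normal
weights with the closed-form parameterization
$\sigma^2 = \log(1 + \mathrm{sd}^2/\mathrm{mean}^2)$,
$\mu = \log(\mathrm{mean}) - \sigma^2/2$, so the arithmetic mean and SD hit
their targets (defaults 9,565 and 11,820, the case-study values) in
expectation. The draws are then comonotonically coupled to a rank driver —
in `draw_survey_sample()`, the base design weight 1/selection probability —
with ties broken by row index. Whether the original study's log-normal
weight draws were coupled to the design or drawn independently is not
documented; coupling is the package's choice, because without
weight–covariate dependence the three scenarios coincide asymptotically and
there would be nothing to study. The simple-random-sample limit is exact:
equal selection probabilities and a zero weight-variance scale produce
constant weights.

### Modification axes

`modify_population()` implements the simulation arms: coefficient scale ×2
and ×0.5, weight variance ×2 and ×0.5, dimensionality reduced to 10
informative predictors (continuous and categorical kept at a ratio
comparable to the full set, selected at random under the spec seed), and
the all-null arm. The intercept is deliberately *not* recalibrated after
modification, matching the design of treating each arm as a perturbation of
the same population.

## Metrics

All metrics derive from weight-summed confusion cells
(`weighted_confusion()`); unit weights recover ordinary counts, and any
integer-weighted metric equals its unweighted counterpart on the
replicate-by-weight expanded data exactly — the suite's strongest oracle.
F1 is computed as `2tp/(2tp+fp+fn)`, with a defined-zero convention for
degenerate cells (no true positives, or no positives at all) so simulation
grids never abort; occurrences are warned about and counted.
Probabilities become classes via an inclusive 0.5 threshold by default; the
threshold is exposed everywhere because the underlying study never states
its rule.

`bootstrap_metric()` computes percentile intervals by resampling
observation-level (y, p̂, w) triples — models are never refit — with
type-7 (linear interpolation) quantiles. Within
`evaluate_scenarios()` the three scenarios share one resample-index
sequence, so bootstrap comparisons are paired. Whether resampled weights
should be renormalized is undocumented in the source study; they are used
as drawn, since F1 is scale-invariant in the weights.

## The configuration engine

`configure_model()` performs a randomized search: candidates are drawn
independently and uniformly over each of 11 hyperparameter ranges
(`hp_space()`), log-uniformly for the learning rate and the L1/L2
penalties because a raw-scale uniform over-samples large values. The
penalties' nominal range starts at 0, where a log-uniform is undefined, so
their draws cover [0.01, 10]. The original study searched 500,000
candidates on an HPC cluster; the package defaults to a desk-scale 60 and
every consumer in the test suite chooses smaller counts still (3–8,
depending on the check), recorded per test. The exact ranges used by the
study are in an unavailable supplement; the ranges here bracket common
practice and are the package's own.

Each candidate is evaluated by outcome-stratified 5-fold cross-validation:
fold sizes differ by at most one, each fold's class mix is within one
observation of proportional, and every row is predicted exactly once by a
model that never saw it. Early stopping monitors log-loss on a seeded 10%
split of the training rows, never the held-out fold. Training weights are
normalized to mean 1 so weighted and unweighted runs face comparable
effective regularization, uniform weights reduce exactly to unweighted
training, and weight rescaling is a no-op. Selection scoring matches the
training mode — the weighted arm picks the candidate with the best
*weighted* OOF F1, the unweighted arm the best unweighted one — reflecting
a pipeline that is weight-aware (or weight-naive) end to end. Ties break
toward the earliest candidate. `default_hyperparameters()` freezes the
boosting library's documented defaults (100 trees, depth 6, learning rate
0.3, no subsampling or L1, L2 = 1), with the early-stopping patience set to
the space's most permissive value (50) since the library default disables
stopping; this supports the default-settings sensitivity analysis without
drift across library versions.

xgboost runs single-threaded with the histogram tree method, which makes
results deterministic for a fixed seed on one platform.

## Scenarios and the error metric

`evaluate_scenarios()` scores Scenario One (weighted configuration,
weighted F1 — the gold standard), Scenario Two (unweighted configuration,
unweighted F1 — the naive analysis) and Scenario Three (unweighted
configuration, weighted F1 — the post-hoc rescue). The two configurations
must come from the same dataset (hash-checked) and, built with the same
seed, share folds and candidates, so scenario differences reflect
weighting, not fold noise. Errors are `(F1 − F1_gold) × 100` percentage
points from unrounded scores; Scenario One's error is identically zero.

## The grid runner

`experiment_grid()` crosses sample sizes (default 250–10,000) with the
seven conditions and a replicate count. The original design ran one dataset
per cell; replication (default 20) is this package's extension, because
directional claims about errors need Monte-Carlo support. Every cell's seed
derives from `(master_seed, condition, n, replicate)` via a stable string
hash (`derive_seed()`), so runs are bitwise reproducible, independent of
execution order and of the number of parallel workers, and any single cell
can be reproduced in isolation. `run_grid()` emits tidy results, aggregate
summaries, a JSON manifest and error-versus-sample-size figures per
condition; `autoplot()` draws the same figure from a result object.

## Numerical choices and degenerate inputs

* Log-normal moment matching is exact in expectation; at n = 10⁵ the
  sample mean sits within ~2% and the SD within ~3% of target (the heavy
  right tail makes the SD the slower-converging moment).
* A draw whose outcome is single-class is retried up to ten times with
  derived seeds, then fails loudly; with calibrated prevalence this is
  only reachable at tiny n.
* Degenerate bootstrap resamples (one class) contribute their defined-zero
  metric and are counted in `n_degenerate`.
* `run_cell()` converts any cell failure into a `status = "failed"` row so
  a grid never dies half-way; the manifest lists failures.

## Problem sizes in the test suite

The shipped tests exercise the directional findings at desk scale, chosen
to keep the full suite within a coffee break on one CPU: the large-n rescue
check runs 20 replicates at n = 5,000 with 8 search candidates per arm; the
near-simple-random-sample and null-floor checks run 20 replicates at
n = 2,500 and n = 1,000 with 3 candidates; predictor-strength monotonicity
runs 10 replicates at n = 5,000 with 3 candidates. Replicate counts and
sample sizes were fixed before the checks were first run; candidate counts
trade tuning depth for runtime and do not enter any assertion.

## What the generator does and does not emulate

It emulates: informative weights of realistic scale and skew, unequal
stratum selection, stratum-shifted mixed-type covariates, a logistic
outcome, and all the modification arms. It does not emulate: multistage
cluster/PSU structure or design-based variance estimation, non-response and
post-stratification adjustment mechanics, real covariate marginals or
their correlation structure, or interactions in the outcome model. Passing
tests therefore demonstrate the *mechanics* of weight-aware configuration
and scoring and the qualitative sample-size patterns, not quantitative
transfer to any particular survey.

## Known limitations

* The ordinal level-score coding of categorical effects understates how
  strongly nominal categories could drive the outcome.
* With strong coupling between weights and covariates, the weighted and
  post-hoc scenarios can be statistically indistinguishable at large n; a
  weight-aware configuration is not guaranteed to dominate the rescored
  naive one, on a single draw or even on average — heavy-tailed training
  weights add variance to the fit, while covariates that encode the strata
  let the unweighted fit post-stratify.
* F1 depends on the outcome prevalence, so scenario errors mix calibration
  and discrimination effects; that mixture is intrinsic to the comparison
  being studied, not an artifact.
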