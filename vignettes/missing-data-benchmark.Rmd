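---
title: "Benchmarking missing-data handling for longitudinal clinical prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking missing-data handling for longitudinal clinical prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gapbench)
```

## The problem

Clinical prediction models built from electronic health records face
pervasive missing data: variables are measured only when clinicians order
them, at irregular intervals, and often *because* the value is expected to
be abnormal. A model deployed for real-time decision support additionally
needs a missing-data strategy that can be *fitted on historical training
data and applied to a single new patient* -- which rules out the usual
refit-everything workflow of classical multiple imputation.

`gapbench` provides the machinery to study this problem end to end on
synthetic pediatric-ICU-like cohorts: ventilated children, 4-hour
observation windows, a binary extubation-success outcome and a continuous
blood-pressure-percentile outcome. Because the pipeline's inputs are
simulated, every stage is testable against known ground truth.

The benchmark has five stages, mirrored by the package modules:

1. **Cohort simulation** (`generate_cohort`) -- raw long-format
   observations with controlled temporal autocorrelation.
2. **Windowing** (`collapse_to_windows`, `build_lagged_matrix`,
   `assign_labels`) -- the 4-hour analysis grid and the lagged wide
   modeling matrix.
3. **Completion** (`complete_table`) -- a fully observed reference table.
4. **Amputation** (`ampute`) -- controlled missingness under
   MCAR / MAR / graded MNAR at multiples of a base cell-wise proportion.
5. **Imputation + prediction + evaluation** (`fit_imputer`,
   `fit_outcome_model`, `imputation_mse`, `prediction_metrics`, ...) --
   six handling strategies, two outcome models, two evaluation levels.

`run_experiment()` drives the full factorial grid from one configuration.

## The generative model

Each intubation event carries a latent severity process $S_k$, a
stationary AR(1) series on the window grid with coefficient $\rho_S = 0.9$
and unit marginal variance. Every time-varying variable $v$ is

$$x_{v,k} = \lambda_v S_k + e_{v,k}, \qquad
  e_{v,k} = \rho_v e_{v,k-1} + \varepsilon_{v,k},$$

with loadings $\lambda_v$ and per-variable autocorrelations $\rho_v$ spread
deterministically across configurable ranges (defaults $[0.2, 0.95]$ for
$\rho_v$, $[0.2, 0.7]$ for $\lambda_v$, assigned in opposite order so the
two axes are not confounded). The shared latent process supplies the
cross-variable correlation that model-based imputers exploit; the
idiosyncratic AR(1) term gives each variable its own temporal stability,
the quantity that carry-forward imputation trades on. Binary time-varying
variables threshold the latent Gaussian at a configurable marginal
prevalence (default 0.3); multi-level categorical variables bin it at
equiprobable quantiles. Both therefore retain meaningful autocorrelation.

Raw observations are emitted at a per-variable cadence of 1-4 hours inside
each window with small measurement jitter (SD 0.05), so the windowing stage
has real aggregation work to do.

**Scale targets.** The default configuration reproduces the structure of
a realistic PICU cohort: 886 patients with a 0.377 reintubation probability
(expected 1220 events); log-normal intubation durations solved from the
median (4.4 days) and the interquartile ratio (2.2-8.5 days; a log-normal
cannot match both quartiles exactly, so the quartile *ratio* is matched);
and a 99-variable census -- 83 time-varying plus 16 static -- chosen so the
two-lag wide matrix has $83 \times 3 + 16 = 265$ feature columns, of which
176 numeric-kind and 6 categorical features are subject to amputation.

**Outcomes.** Extubation success follows a logistic model on late-window
severity (the mean of $S_k$ over the final three windows, slope $-1.2$:
sicker patients fail). The intercept is never hard-coded: it is solved by
bisection (`calibrate_outcome_intercept`) so the event-level prevalence
matches the 76.1% target. Non-success events are assigned terminal
categories (reintubation, death, tracheostomy, transfer, tube change) at
fixed realistic conditional frequencies. The continuous outcome is a
blood-pressure percentile, $100\,\Phi(-0.7\,S_k + \epsilon_k)$, read one
window ahead; the binary label of window $k$ is 1 exactly when the event
ends in successful extubation by the end of window $k+3$ (a patient still
intubated at the horizon counts as not-yet-successful -- terminal status is
the status thereafter).

## Windowing conventions

Window $k$ covers the half-open interval $(4(k-1), 4k]$ hours after
intubation, indexed from 1, so window boundaries partition the intubation
period and no observation is counted twice; an observation at exactly the
intubation time falls outside every window and is dropped with a warning.
Numeric and binary cells take the in-window mean, categorical cells the
mode with ties broken by the most recent observation (the latest clinical
assessment wins; the choice is invisible for the default cadences but must
be fixed). Events intubated 24 hours or less are excluded (strictly: a
24.0-hour event is excluded, 24.5 is retained). The first two windows of
each event exist only to supply lags; the first eligible modeling row is
window 3, ending 12 hours after intubation. Partial final windows are kept
when they contain at least one observation. Events are never truncated.

## Completion

The reference ("synthetic complete") table is built by a fixed pipeline --
linear interpolation of interior numeric gaps on the window index, then
nearest-observed fill within the event (ties to the earlier neighbor),
then deterministic formula fallbacks (the pediatric tube-size formula
age/4 + 4), then random-forest donor imputation fitted on the table itself.
Interpolation runs on the window index rather than raw timestamps because
windows are the analysis grid; categorical series skip interpolation
(undefined between levels) and go straight to nearest fill, which preserves
level validity. Each step only ever fills cells, never alters observed
ones, and the output is certified gap-free. Per-cell provenance codes
(observed / interpolated / nearest / formula / model) are retained and feed
the originally-missing stratification of the evaluation module.

## Amputation

A scenario is a mechanism crossed with a proportion level (0.5x, 1x, 2x a
base cell-wise proportion, default 0.182). Patterns come from the census's
five variable groups; group 4 is a block of "select all that apply"
indicator variables. Each pattern is applied independently to every row:
rows are scored by a weighted sum of standardized values -- weights per
mechanism: MAR puts unit weight on the observed complement (plus the
outcome), weak/moderate/strong MNAR weight observed:amputed at 2:1, 1:1 and
0:1 -- and a shifted-logistic allocation calibrated by bisection converts
scores to Bernoulli probabilities. Independent per-pattern application
(rather than assigning each row to a single pattern) is what makes the 2x
level reachable: with disjoint single-group patterns a row can lose at most
one group's cells, capping the expected cell proportion near 12%, whereas
windowed EHR rows routinely miss several blocks at once. The common row
probability is derived from the pattern sizes so the *expected* cell-wise
proportion over all predictor cells equals the target exactly; the
achieved proportion of every draw is recorded. MCAR ignores the scores;
the outcome enters the weighted sum with unit weight for MAR and all MNAR
variants. Masks are confined to amputable cells, and lagged features
inherit exactly the base window's mask (amputation precedes lag
construction).

## Imputation strategies

All six strategies obey one contract: state is learned from training rows
only, never from the outcome, and applying to new rows -- including a
single row -- requires no refitting.

* **mean** -- unconditional training mean / mode.
* **locf** -- last observation carried forward indefinitely within an
  event, on the base series, with lags rebuilt afterwards (temporal
  consistency); leading gaps stay missing unless the training-mean fallback
  is enabled for complete-data outcome models.
* **rf_donor** -- one random forest per variable; a donor is drawn from the
  training observations sharing a terminal node with the target (tree
  sampled uniformly, then a donor within its leaf, i.e. uniform over the
  pooled leaf multiset), so imputed values are always observed values.
* **bayes_pmm** -- Bayesian normal linear model on standardized predictors
  with a small ridge ($10^{-5}$) for stability; coefficients drawn from the
  conjugate normal-inverse-gamma posterior; predictive mean matching
  against the 5 prediction-nearest training donors (type-1 matching:
  donor predictions from the posterior mean, target predictions from the
  draw), guaranteeing range containment.
* **lasso_boot** -- the L1 penalty is chosen once per variable by 5-fold
  cross-validation on observed training rows; each of the m imputations
  refits the penalized model on a fresh bootstrap sample and adds a
  Gaussian residual draw. Multi-level categorical responses, which the
  linear machinery cannot accommodate, use a classification tree with leaf
  frequencies sampled (the same tree path serves bayes_pmm's categorical
  case).
* **none** -- passthrough for outcome models with native missing-value
  routing.

Model-based methods are trained by chained equations: missing cells are
initialized at training means/modes, variables are visited in order of
increasing missingness, and the cycle sweeps `chained_iters` times
(default 5; the reduced test configurations use 2). The final sweep's
models and donor pools are stored; application re-runs the sweeps against
the frozen models with fresh stochastic draws, once per imputation
(default m = 30). Each lagged copy is treated as a distinct variable, so
copies of one underlying measurement may receive different imputations --
accepted, as the flat-wide representation implies. Averaging the m
completions (numeric mean, categorical per-cell mode) gives the stable
single-table variant; keeping them separate gives the multiple-imputation
ensemble.

## Outcome models

Gradient boosted trees (xgboost; missing cells routed natively to the
loss-optimal side of each split) and an L1-penalized linear/logistic model
(glmnet; requires complete input and refuses anything else).
Hyperparameters are tuned by 5-fold cross-validation inside the training
partition with folds grouped by event, so windows of one event never
straddle folds; binary tasks weight classes by inverse frequency. The
default boosting grid is learning rate {0.05, 0.1} by depth {3, 5} with
rounds chosen by early stopping; the classification threshold for class
metrics is 0.5 (configurable). The train/test split is chronological at
75/25 with patient exclusivity, implemented by ordering patients by their
earliest intubation and accumulating whole patients until the event target
is reached -- a straddling patient therefore follows their earliest event,
and the training share is within one patient's events of 75%.

## Evaluation

Imputation accuracy: per-variable mean squared error on amputed cells,
standardized by the variable's SD in the complete dataset (computed once),
averaged unweighted over variables with at least one amputed cell --
variables, not cells, are the unit, matching how per-variable error
profiles are read. Categorical variables contribute a classification
error. Multiply imputed methods are averaged before scoring. Prediction:
balanced accuracy and AUC as primary binary metrics (sensitivity,
specificity, PPV, NPV, F1 secondary), MSE/RMSE/MAE/R² for the continuous
outcome, coefficient of variation across methods (sample SD over mean of
per-method means, pooled over scenarios) and train-minus-test overfit
gaps. Temporal autocorrelation is estimated as the pooled within-event
lag-1 Pearson correlation (boundary pairs dropped) and correlated, across
variables, with per-variable error.

## Problem sizes used by the tests and the acceptance script

The test suite runs the full pipeline at sizes chosen for a single CPU:

* Generator-scale checks (amputation calibration at every mechanism and
  level; the variance identity of mean imputation) use a cohort with the
  full 99-variable census, ~75 events and >= 50,000 amputable cells, with
  20 amputation replicates per scenario.
* The headline-direction suite uses a 30-event cohort with 10 amputable
  numeric time-varying variables whose $\rho_v$ span $[0.6, 0.95]$,
  MCAR at levels {0.5, 1, 2} with 10 replicates, m = 10,
  2 chained-equation sweeps and 50-tree forests. MCAR is used deliberately:
  under MAR/MNAR the score-based selection of amputed cells changes *which*
  cells are missing as the level rises, confounding the pure effect of the
  missingness proportion that the degradation property describes.
* Prevalence and duration calibration run at 1,220-5,000 events through
  the event-level fast path (`generate_events`), which skips the raw
  observation stream.

On this desk-scale grid the suite reproduces the benchmark's headline
directions: carry-forward imputation has the lowest standardized MSE,
forest-donor imputation is second, mean imputation worst; every
model-based imputer degrades monotonically as the missing proportion
doubles; and carry-forward error correlates strongly negatively with
per-variable autocorrelation. The tests assert these orderings; no
numerical result is claimed beyond what they compute.

## What the synthetic cohort does and does not show

The generator reproduces the *structure* that drives missing-data method
behavior -- temporal autocorrelation, cross-variable correlation through a
latent severity, mixed variable kinds, static blocks, outcome-linked
missingness, realistic event counts and durations -- but not clinical
content: individual variables have no units, reference ranges, or
pharmacology, and the joint distribution is linear-Gaussian at its core.
Conclusions about *relative method behavior as a function of structure*
transfer; absolute error magnitudes and any behavior driven by strong
nonlinearity in real physiology do not. Passing tests certify the
machinery and the direction of effects, not clinical performance.

## Numerical choices and degenerate inputs

Bisection tolerances: 1e-10 on the outcome-intercept prevalence, 1e-9 on
the amputation probability offset. Zero-variance variables are dropped from
amputation scores and from standardized MSE, with warnings. A variable with
no observed training values falls back to a census-level default (0 /
first level) with a message; unseen categorical levels at application time
map to the training mode with a message. An imputer refuses to fit if
outcome columns are present and not explicitly excluded. Requesting a cell
proportion above the amputable fraction is an error, never a silent clip.
Single-class training labels and single-class AUC are explicit errors /
NA. All randomness flows from explicit integer seeds; the experiment
driver derives a child seed for every (outcome, scenario, replicate,
method) cell with a counter-based scheme kept below $2^{31}$, so any cell
is reproducible in isolation.

## Known limitations

Chained equations use all other columns as predictors for every variable;
at the full 265-feature scale this is the dominant cost, and no
predictor pre-selection is applied. The Bayesian-PMM posterior is the
conjugate one on standardized predictors, a conventional stand-in for
whatever scheme a particular package implements. LOCF's strong showing is
partly structural: the completion step itself favors temporally stable
reconstructions, which the originally-missing stratification quantifies.
Deep-learning imputers, multilevel imputation models, and
stack-with-training-data workarounds are out of scope by design.
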