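# gapbench

Benchmarking missing-data handling for longitudinal clinical prediction.

Electronic health records are measured when clinicians order tests, not on
a schedule, so the windowed tables behind clinical prediction models are
riddled with gaps — and a model meant for real-time decision support needs
a missing-data strategy that can be **fitted on training data and applied
to one new patient at a time**, which classical refit-everything multiple
imputation cannot do. `gapbench` implements, as reusable and tested
machinery, a full experimental pipeline for studying this problem on
synthetic pediatric-ICU-like cohorts:

1. **Cohort simulation** — raw long-format observations for ~1220
   intubation events. Each event carries a latent severity process
   S_k (AR(1), ρ = 0.9); variable v follows
   x_{v,k} = λ_v·S_k + e_{v,k} with e_{v,k} an independent AR(1) series,
   so variables are temporally autocorrelated and cross-correlated. The
   extubation-success outcome is logistic in late-window severity with the
   intercept solved by bisection to a 76.1% prevalence; a continuous
   blood-pressure-percentile outcome reads 100·Φ(−0.7·S_k + ε).
2. **Windowing** — half-open 4-hour windows (mean / latest-wins mode),
   eligibility rules (>24 h intubations), a 2-lag wide matrix
   (99 variables → 265 features), and labels read 3 windows (binary) or
   1 window (continuous) ahead.
3. **Completion** — a gap-free reference table via linear interpolation →
   nearest-value fill → formula fallbacks (tube size = age/4 + 4) →
   random-forest donor imputation, with per-cell provenance.
4. **Amputation** — MCAR, MAR and weak/moderate/strong MNAR at 0.5×/1×/2×
   a base cell-wise proportion (default 18.2%), via weighted-sum scores on
   variable-group patterns with observed:amputed weight ratios 1:0, 2:1,
   1:1, 0:1 and a bisection-calibrated shifted-logistic allocation.
5. **Imputation** — six transferable strategies (mean, last observation
   carried forward, random-forest donor sampling, Bayesian predictive mean
   matching, bootstrap-LASSO, and none/native) trained by chained
   equations on training rows only, never the outcome; m = 30 imputations
   averaged or ensembled.
6. **Prediction & evaluation** — gradient boosted trees (native missing
   support) and L1 models with event-grouped 5-fold CV and inverse
   frequency weights; standardized imputation MSE and classification
   error; balanced accuracy, AUC and friends; autocorrelation–error and
   originally-missing analyses.

`run_experiment()` drives the whole factorial grid
(mechanism × level × replicate × method × model × outcome) from one
config with fully derived child seeds.

## Worked example

Generate a desk-scale cohort, knock out 18.2% of cells completely at
random, and compare three handling strategies on the chronologically held
out test quarter:

```r
library(gapbench)

cfg  <- experiment_config("desk", seed = 42)
prep <- prepare_experiment_data(cfg)      # 66 events, 1197 window rows

scen <- missingness_scenario("MCAR", level = 1, seed = 1)
amp  <- ampute(prep$complete, scen, prep$census)
amp$achieved_cell_proportion              # 0.181

wide  <- build_lagged_matrix(prep$complete, cfg$wspec, prep$census)
wmask <- lag_mask(amp$mask, prep$complete, wide, cfg$wspec)
test  <- !(wide$event_id %in% prep$split$train)
ctx   <- eval_context(wide[test, ], wmask[test, ], prep$census)

for (method in c("mean", "locf", "rf_donor")) {
  imp <- impute_dataset(method, amp$data, prep$complete, prep$split,
                        prep$census, cfg$wspec, m = 10, seed = 2,
                        imputer_args = cfg$imputer_args)
  avg   <- imp$test$average
  cells <- ctx$mask & !vapply(colnames(ctx$mask),
                              function(v) is.na(avg[[v]]), logical(nrow(avg)))
  cat(sprintf("%-9s standardized MSE: %.3f\n", method,
              imputation_mse(ctx, avg, cells = cells)$overall))
}
#> mean      standardized MSE: 0.992
#> locf      standardized MSE: 0.655
#> rf_donor  standardized MSE: 0.646
```

Mean imputation sits at the variance identity (≈1 under MCAR); the
temporal methods cut the error by a third because these variables are
strongly autocorrelated (ρ ∈ [0.6, 0.95] in the desk census). The full
benchmark — all mechanisms, levels, methods and outcome models — is one
call:

```r
report <- run_experiment(experiment_config("desk", seed = 1))
variability_and_overfit(report, "balanced_accuracy")$cv
```

A thin CLI over the same functions lives at `inst/cli/gapbench.R`
(`generate` and `run-all` subcommands).

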