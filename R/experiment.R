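#' Experiment configuration
#'
#' Drives the full factorial benchmark: mechanism x proportion level x
#' replicate x handling method x outcome model x outcome. The `"paper"`
#' preset runs the full benchmark grid (5 mechanisms, levels 0.5/1/2, 20
#' replicates, m = 30, both outcomes); the `"desk"` preset is a reduced grid
#' sized for interactive runs and continuous testing.
#'
#' @param preset `"desk"` or `"paper"`; individual arguments override the
#'   preset.
#' @param generator a [generator_config()].
#' @param wspec a [window_spec()].
#' @param mechanisms,levels scenario grid.
#' @param replicates amputed datasets per scenario.
#' @param base_cell_proportion base cell-wise missing proportion.
#' @param methods handling methods to compare.
#' @param m imputations per dataset for stochastic methods.
#' @param imputer_args extra arguments passed to [imputer_spec()].
#' @param outcomes `"binary"`, `"continuous"`, or both.
#' @param models outcome learners (`"gbt"`, `"l1"`).
#' @param model_args extra arguments passed to [outcome_model_spec()].
#' @param mi_variants also run the multiple-imputation ensemble route for
#'   stochastic methods.
#' @param train_fraction chronological training share.
#' @param seed master seed; every scenario/replicate/method cell derives its
#'   own child seed from it.
#' @return an object of class `gb_experiment_config`.
#' @export
experiment_config <- function(preset = c("desk", "paper"),
                              generator = NULL, wspec = window_spec(),
                              mechanisms = NULL, levels = NULL,
                              replicates = NULL,
                              base_cell_proportion = 0.182,
                              methods = NULL, m = NULL,
                              imputer_args = list(),
                              outcomes = "binary",
                              models = "gbt", model_args = list(),
                              mi_variants = TRUE,
                              train_fraction = 0.75, seed = 1L) {
  preset <- match.arg(preset)
  all_mech <- c("MCAR", "MAR", "MNAR_weak", "MNAR_moderate", "MNAR_strong")
  all_methods <- c("mean", "locf", "rf_donor", "bayes_pmm", "lasso_boot", "none")
  if (preset == "paper") {
    generator <- generator %||% generator_config(seed = seed)
    mechanisms <- mechanisms %||% all_mech
    levels <- levels %||% c(0.5, 1, 2)
    replicates <- replicates %||% 20L
    methods <- methods %||% all_methods
    m <- m %||% 30L
  } else {
    generator <- generator %||% generator_config(
      n_patients = 60, reintubation_prob = 0.2,
      duration_median_days = 2, duration_iqr_days = c(1.2, 3.4),
      census = make_census(n_numeric_tv = 10, n_binary_tv = 2,
                           n_categorical_tv = 1, n_levels = 4L,
                           n_numeric_tv_fixed = 2, n_binary_tv_fixed = 0,
                           n_static_amputable = 2, n_static_fixed = 1,
                           ar1_range = c(0.6, 0.95)),
      seed = seed)
    mechanisms <- mechanisms %||% c("MCAR", "MNAR_strong")
    levels <- levels %||% c(1)
    replicates <- replicates %||% 5L
    methods <- methods %||% c("mean", "locf", "rf_donor", "none")
    m <- m %||% 10L
    imputer_args <- utils::modifyList(
      list(n_trees = 50L, chained_iters = 2L), imputer_args)
    model_args <- utils::modifyList(
      list(eta = 0.1, max_depth = 3L, nrounds_max = 60L), model_args)
  }
  structure(list(preset = preset, generator = generator, wspec = wspec,
                 mechanisms = mechanisms, levels = levels,
                 replicates = as.integer(replicates),
                 base_cell_proportion = base_cell_proportion,
                 methods = methods, m = as.integer(m),
                 imputer_args = imputer_args,
                 outcomes = outcomes, models = models, model_args = model_args,
                 mi_variants = mi_variants,
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "gb_experiment_config")
}

#' Enumerate the missingness scenario grid
#'
#' @param config a [experiment_config()].
#' @return data frame with one row per mechanism x level, deterministically
#'   ordered (mechanism outer, level inner).
#' @export
enumerate_scenarios <- function(config) {
  if (length(config$mechanisms) == 0L || length(config$levels) == 0L)
    stop("mechanism and level lists must be nonempty")
  grid <- expand.grid(level = config$levels, mechanism = config$mechanisms,
                      stringsAsFactors = FALSE)[, c("mechanism", "level")]
  grid$scenario_idx <- seq_len(nrow(grid))
  grid
}

## counter-based child seeds: any cell of the grid is reproducible in
## isolation; kept below 2^31
child_seed <- function(master, ...) {
  idx <- c(...)
  x <- as.double(master) %% 2147483647
  for (k in idx) x <- (x * 48271 + as.double(k) * 104729 + 1) %% 2147483647
  as.integer(x) + 1L
}

#' Prepare the shared experiment inputs
#'
#' Generates the cohort, applies eligibility filtering, collapses to
#' windows, optionally punches and refills "original-mode" gaps (recording
#' originally-missing flags), and assigns labels; then computes the
#' chronological split.
#'
#' @param config a [experiment_config()].
#' @return list: `complete` (labeled complete window table), `events`,
#'   `census`, `split`, `original_flags` (or NULL).
#' @export
prepare_experiment_data <- function(config) {
  cohort <- generate_cohort(config$generator)
  events <- filter_eligible_events(cohort$events, config$wspec)
  cohort$events <- events
  wt <- collapse_to_windows(cohort, config$wspec)
  census <- cohort$census

  original_flags <- NULL
  if (!is.null(config$generator$original_missingness)) {
    om <- induce_original_missingness(wt, config$generator, census)
    comp <- complete_table(om$table, census, seed = config$seed)
    wt <- comp$table
    original_flags <- om$flags
  } else {
    gap_vars <- census$name[census$name %in% names(wt)]
    if (anyNA(wt[gap_vars])) {
      comp <- complete_table(wt, census, seed = config$seed)
      wt <- comp$table
    }
  }
  wt <- assign_labels(wt, events, config$wspec)
  split <- chronological_split(events, config$train_fraction)
  list(complete = wt, events = events, census = census, split = split,
       original_flags = original_flags)
}

## fill any residual missing cells with training means/modes (used to feed
## LOCF output into complete-data outcome models)
mean_fallback_fill <- function(df, fitted) init_fill(df, fitted)

#' Impute one amputed dataset with one method
#'
#' Dispatches on the method's natural representation: LOCF fills the base
#' window table and the lagged matrix is rebuilt from it (temporal
#' consistency); every other method operates on the lagged wide matrix with
#' each lagged copy treated as a distinct variable. The fit uses training
#' rows only and never sees the outcome.
#'
#' @param method method name.
#' @param amputed_wt amputed window table (all windows).
#' @param complete_wt the complete window table; reserved for provenance --
#'   imputation never reads its values (the fit sees only `amputed_wt`'s
#'   training rows).
#' @param split chronological split (train/test event ids).
#' @param census the census.
#' @param wspec the window spec.
#' @param m imputations.
#' @param seed seed.
#' @param imputer_args extra [imputer_spec()] arguments.
#' @return list with `train` and `test` `gb_imputed_bundle`s over the wide
#'   matrix, and `fitted`.
#' @export
impute_dataset <- function(method, amputed_wt, complete_wt, split, census,
                           wspec = window_spec(), m = 10L, seed = 1L,
                           imputer_args = list()) {
  spec <- do.call(imputer_spec, c(list(method = method, m = m, seed = seed),
                                  imputer_args))
  label_cols <- grep("^label_", names(amputed_wt), value = TRUE)

  if (method == "locf") {
    base_cols <- c("event_id", "patient_id", "window_index", "n_windows",
                   "eligible", census_predictors(census))
    base_cols <- intersect(base_cols, names(amputed_wt))
    tr_rows <- amputed_wt$event_id %in% split$train
    fitted <- fit_imputer(spec, amputed_wt[tr_rows, base_cols, drop = FALSE])
    fill_part <- function(rows_idx) {
      part <- apply_imputer(fitted, amputed_wt[rows_idx, base_cols, drop = FALSE],
                            seed = seed + 7L)$average
      part[label_cols] <- amputed_wt[rows_idx, label_cols, drop = FALSE]
      wide <- build_lagged_matrix(part, wspec, census)
      mask_cols <- attr(wide, "feature_cols")
      bundle <- list(imputations = list(wide), average = wide, m = 1L,
                     method = "locf",
                     cell_mask = is.na(as.matrix(wide[mask_cols])))
      class(bundle) <- "gb_imputed_bundle"
      bundle
    }
    return(list(train = fill_part(tr_rows), test = fill_part(!tr_rows),
                fitted = fitted))
  }

  wide_amp <- build_lagged_matrix(amputed_wt, wspec, census)
  tr <- wide_amp$event_id %in% split$train
  train_rows <- wide_amp[tr, , drop = FALSE]
  test_rows <- wide_amp[!tr, , drop = FALSE]
  attr(train_rows, "feature_cols") <- attr(wide_amp, "feature_cols")
  attr(test_rows, "feature_cols") <- attr(wide_amp, "feature_cols")
  fitted <- fit_imputer(spec, train_rows, census = census,
                        exclude = label_cols)
  strip <- function(df) df[, setdiff(names(df), label_cols), drop = FALSE]
  restore <- function(bundle, src) {
    bundle$imputations <- lapply(bundle$imputations, function(d) {
      d[label_cols] <- src[, label_cols, drop = FALSE]
      attr(d, "feature_cols") <- attr(src, "feature_cols")
      d
    })
    bundle$average[label_cols] <- src[, label_cols, drop = FALSE]
    attr(bundle$average, "feature_cols") <- attr(src, "feature_cols")
    bundle
  }
  btr <- apply_imputer(fitted, strip(train_rows), m = m, seed = seed + 11L)
  bte <- apply_imputer(fitted, strip(test_rows), m = m, seed = seed + 13L)
  list(train = restore(btr, train_rows), test = restore(bte, test_rows),
       fitted = fitted)
}

#' Run the full benchmark
#'
#' For each outcome: build the complete labeled table, split
#' chronologically, then for every scenario x replicate ampute the window
#' table (outcome allowed to influence missingness outside MCAR), apply
#' every handling method (fit on train, apply to train and test), fit
#' outcome models on the averaged imputation (and, for stochastic methods,
#' the m-member multiple-imputation ensemble), and collect imputation-error
#' and prediction-metric rows in tidy form.
#'
#' @param config a [experiment_config()].
#' @return a tidy data frame (`gb_report`): outcome, mechanism, level,
#'   replicate, method, variant, model, partition, metric, value.
#' @export
run_experiment <- function(config) {
  prep <- prepare_experiment_data(config)
  wspec <- config$wspec
  census <- prep$census
  complete_wt <- prep$complete
  split <- prep$split
  scen_grid <- enumerate_scenarios(config)
  pred_cols <- intersect(census_predictors(census), names(complete_wt))

  wide_complete <- build_lagged_matrix(complete_wt, wspec, census)
  feat_cols <- attr(wide_complete, "feature_cols")
  rows <- list()
  add_row <- function(...) rows[[length(rows) + 1L]] <<- data.frame(...)

  for (outcome in config$outcomes) {
    label_col <- if (outcome == "binary") "label_success" else "label_bp"
    out_vec <- if (outcome == "binary") {
      prep$events$success[match(complete_wt$event_id, prep$events$event_id)]
    } else complete_wt[["bp_percentile"]]

    for (s in seq_len(nrow(scen_grid))) {
      for (rep_i in seq_len(config$replicates)) {
        sc_seed <- child_seed(config$seed, match(outcome, config$outcomes),
                              s, rep_i)
        scen <- missingness_scenario(scen_grid$mechanism[s],
                                     level = scen_grid$level[s],
                                     base_cell_proportion = config$base_cell_proportion,
                                     seed = sc_seed)
        amp <- ampute(complete_wt, scen, census, outcome = out_vec)
        wmask <- lag_mask(amp$mask, complete_wt, wide_complete, wspec)
        tr_idx <- wide_complete$event_id %in% split$train

        ctx <- list(
          train = eval_context(wide_complete[tr_idx, , drop = FALSE],
                               wmask[tr_idx, , drop = FALSE], census),
          test = eval_context(wide_complete[!tr_idx, , drop = FALSE],
                              wmask[!tr_idx, , drop = FALSE], census))

        for (method in config$methods) {
          m_seed <- child_seed(sc_seed, match(method, config$methods))
          imp <- impute_dataset(method, amp$data, complete_wt, split, census,
                                wspec, m = config$m, seed = m_seed,
                                imputer_args = config$imputer_args)

          if (method != "none") {
            for (part in c("train", "test")) {
              avg <- imp[[part]]$average
              cells <- ctx[[part]]$mask
              filled <- !vapply(colnames(cells), function(v) is.na(avg[[v]]),
                                logical(nrow(avg)))
              cells <- cells & filled
              if (any(cells[, names(ctx[[part]]$kinds)[ctx[[part]]$kinds == "numeric"]])) {
                mse <- imputation_mse(ctx[[part]], avg, cells = cells)
                add_row(outcome = outcome, mechanism = scen$mechanism,
                        level = scen$level, replicate = rep_i, method = method,
                        variant = "averaged", model = NA_character_,
                        partition = part, metric = "imputation_mse",
                        value = mse$overall)
              }
              if (any(ctx[[part]]$kinds == "categorical") &&
                  any(cells[, names(ctx[[part]]$kinds)[ctx[[part]]$kinds == "categorical"],
                            drop = FALSE])) {
                ce <- classification_error(ctx[[part]], avg, cells = cells)
                add_row(outcome = outcome, mechanism = scen$mechanism,
                        level = scen$level, replicate = rep_i, method = method,
                        variant = "averaged", model = NA_character_,
                        partition = part, metric = "classification_error",
                        value = ce$overall)
              }
            }
          }

          for (model in config$models) {
            if (model == "l1" && method == "none") next
            task <- if (outcome == "binary") "binary" else "continuous"
            ospec <- do.call(outcome_model_spec,
                             c(list(learner = model, task = task,
                                    seed = child_seed(m_seed, 1L)),
                               config$model_args))
            run_variant <- function(variant, tr_list, te_list) {
              tr1 <- tr_list[[1]]
              prep_rows <- function(d) {
                if (model == "l1") mean_fallback_fill(d, imp$fitted) else d
              }
              models <- lapply(tr_list, function(d) {
                d <- prep_rows(d)
                fit_outcome_model(ospec, d, d[[label_col]],
                                  feature_cols = feat_cols)
              })
              for (part in c("train", "test")) {
                dl <- if (part == "train") tr_list else te_list
                dl <- lapply(dl, prep_rows)
                scores <- mi_ensemble_predict(models, dl)
                labs <- dl[[1]][[label_col]]
                mets <- prediction_metrics(labs, scores, task,
                                           threshold = ospec$threshold)
                for (mn in names(mets)) {
                  add_row(outcome = outcome, mechanism = scen$mechanism,
                          level = scen$level, replicate = rep_i,
                          method = method, variant = variant, model = model,
                          partition = part, metric = mn, value = mets[[mn]])
                }
              }
            }
            run_variant("averaged", list(imp$train$average), list(imp$test$average))
            if (config$mi_variants && !is_deterministic_method(method) &&
                imp$train$m > 1L) {
              run_variant("mi", imp$train$imputations, imp$test$imputations)
            }
          }
        }
      }
    }
  }
  report <- do.call(rbind, rows)
  class(report) <- c("gb_report", "data.frame")
  report
}

#' Write an evaluation report as tidy CSV
#'
#' @param report a `gb_report`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  data.table::fwrite(as.data.frame(report), path)
  invisible(path)
}
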