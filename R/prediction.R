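#' Outcome model specification
#'
#' The two outcome models: gradient boosted trees (`gbt`), which route
#' missing cells natively to the loss-optimal side of each split, and an
#' L1-penalized linear/logistic model (`l1`), which requires complete input.
#' Hyperparameters are tuned by 5-fold cross-validation within the training
#' set, with folds grouped by intubation event so no event's windows are ever
#' split across folds; binary tasks upweight the minority class by inverse
#' class frequency.
#'
#' @param learner `"gbt"` or `"l1"`.
#' @param task `"binary"` or `"continuous"`.
#' @param cv_folds number of CV folds (default 5).
#' @param threshold classification threshold for class metrics (default 0.5).
#' @param eta,max_depth tuning grid for gbt (all combinations tried; number
#'   of rounds chosen by early stopping on the CV loss).
#' @param nrounds_max,early_stopping gbt boosting-round controls.
#' @param seed integer seed (fold assignment and learner).
#' @return an object of class `gb_outcome_spec`.
#' @export
outcome_model_spec <- function(learner = c("gbt", "l1"),
                               task = c("binary", "continuous"),
                               cv_folds = 5L, threshold = 0.5,
                               eta = c(0.05, 0.1), max_depth = c(3L, 5L),
                               nrounds_max = 300L, early_stopping = 20L,
                               seed = 1L) {
  structure(list(learner = match.arg(learner), task = match.arg(task),
                 cv_folds = as.integer(cv_folds), threshold = threshold,
                 eta = eta, max_depth = as.integer(max_depth),
                 nrounds_max = as.integer(nrounds_max),
                 early_stopping = as.integer(early_stopping),
                 seed = as.integer(seed)),
            class = "gb_outcome_spec")
}

#' Inverse-frequency class weights
#'
#' Weights proportional to 1 / class frequency, normalized to mean 1, so the
#' weighted mass of each class is equal.
#'
#' @param y binary 0/1 labels.
#' @return numeric weight per observation.
#' @export
inverse_frequency_weights <- function(y) {
  tab <- table(factor(y, levels = c(0, 1)))
  if (any(tab == 0)) stop("training labels contain a single class")
  w <- as.numeric(sum(tab) / (2 * tab[as.character(y)]))
  w
}

## event-grouped fold ids: every window row of an event lands in one fold
grouped_foldid <- function(groups, k) {
  ev <- unique(groups)
  fold_of_ev <- stats::setNames(sample(rep_len(seq_len(k), length(ev))), ev)
  as.integer(fold_of_ev[as.character(groups)])
}

feature_matrix <- function(rows, feature_cols) {
  df <- rows[, feature_cols, drop = FALSE]
  for (v in names(df)) if (is.factor(df[[v]])) df[[v]] <- as.numeric(df[[v]])
  as.matrix(df)
}

#' Fit an outcome model
#'
#' @param spec an [outcome_model_spec()].
#' @param rows training rows (features + ids).
#' @param labels numeric outcome vector (0/1 for binary).
#' @param feature_cols feature column names (default: attribute of `rows`,
#'   else every non-id, non-label column).
#' @param groups grouping vector for CV folds (default `rows$event_id`).
#' @return an object of class `gb_outcome_model`.
#' @export
fit_outcome_model <- function(spec, rows, labels,
                              feature_cols = NULL, groups = NULL) {
  stopifnot(inherits(spec, "gb_outcome_spec"))
  feature_cols <- feature_cols %||% attr(rows, "feature_cols") %||% modeling_columns(rows)
  groups <- groups %||% rows$event_id %||% seq_along(labels)
  keep <- !is.na(labels)
  rows <- rows[keep, , drop = FALSE]
  labels <- labels[keep]
  groups <- groups[keep]
  x <- feature_matrix(rows, feature_cols)
  if (spec$task == "binary" && length(unique(labels)) < 2L)
    stop("training labels contain a single class")

  set.seed(spec$seed)
  foldid <- grouped_foldid(groups, spec$cv_folds)
  w <- if (spec$task == "binary") inverse_frequency_weights(labels) else
    rep(1, length(labels))

  if (spec$learner == "l1") {
    if (anyNA(x))
      stop("the L1 outcome model cannot accommodate missing values; impute first")
    cv <- glmnet::cv.glmnet(
      x, labels, weights = w, foldid = foldid,
      family = if (spec$task == "binary") "binomial" else "gaussian")
    fitted <- list(cv = cv, lambda = cv$lambda.min)
    chosen <- list(lambda = cv$lambda.min)
  } else {
    params_grid <- expand.grid(eta = spec$eta, max_depth = spec$max_depth)
    folds <- split(seq_along(labels), foldid)
    obj <- if (spec$task == "binary") "binary:logistic" else "reg:squarederror"
    metric <- if (spec$task == "binary") "logloss" else "rmse"
    dm <- xgboost::xgb.DMatrix(x, label = labels, weight = w, nthread = 1L)
    best <- NULL
    for (i in seq_len(nrow(params_grid))) {
      cvres <- xgboost::xgb.cv(
        params = list(objective = obj, eta = params_grid$eta[i],
                      max_depth = params_grid$max_depth[i],
                      eval_metric = metric, nthread = 1L,
                      seed = spec$seed),
        data = dm, folds = folds, nrounds = spec$nrounds_max,
        early_stopping_rounds = spec$early_stopping, verbose = 0)
      log <- cvres$evaluation_log[[paste0("test_", metric, "_mean")]]
      score <- min(log)
      if (is.null(best) || score < best$score) {
        best <- list(score = score, eta = params_grid$eta[i],
                     max_depth = params_grid$max_depth[i],
                     nrounds = which.min(log))
      }
    }
    booster <- xgboost::xgb.train(
      params = list(objective = obj, eta = best$eta,
                    max_depth = best$max_depth, eval_metric = metric,
                    nthread = 1L, seed = spec$seed),
      data = dm, nrounds = best$nrounds, verbose = 0)
    fitted <- list(booster = booster)
    chosen <- best[c("eta", "max_depth", "nrounds")]
  }

  structure(list(learner = spec$learner, task = spec$task, spec = spec,
                 fitted = fitted, chosen = chosen,
                 feature_cols = feature_cols,
                 class_freq = if (spec$task == "binary") table(labels) else NULL),
            class = "gb_outcome_model")
}

#' Predict from a fitted outcome model
#'
#' @param object a `gb_outcome_model`.
#' @param newdata rows sharing the training feature columns.
#' @param ... unused.
#' @return binary task: probabilities in 0..1; continuous task: real values.
#' @export
predict.gb_outcome_model <- function(object, newdata, ...) {
  x <- feature_matrix(newdata, object$feature_cols)
  if (object$learner == "l1") {
    if (anyNA(x)) stop("the L1 outcome model cannot accommodate missing values")
    as.numeric(stats::predict(object$fitted$cv, newx = x, s = "lambda.min",
                              type = "response"))
  } else {
    as.numeric(stats::predict(object$fitted$booster,
                              xgboost::xgb.DMatrix(x, nthread = 1L, missing = NA)))
  }
}

#' Ensemble prediction over multiply imputed datasets
#'
#' The multiple-imputation route: one outcome model per imputed training set,
#' each applied to its matching imputed test set; the final score is the
#' arithmetic mean of the member scores (probabilities for binary tasks,
#' values for continuous).
#'
#' @param models list of m `gb_outcome_model`s.
#' @param rows_list list of m matching test data frames (or a single data
#'   frame reused for every member).
#' @return numeric vector of ensembled scores.
#' @export
mi_ensemble_predict <- function(models, rows_list) {
  if (is.data.frame(rows_list)) rows_list <- rep(list(rows_list), length(models))
  if (length(models) != length(rows_list))
    stop("number of models and of imputed test sets differ")
  preds <- mapply(function(mdl, rws) predict(mdl, rws),
                  models, rows_list, SIMPLIFY = TRUE)
  rowMeans(matrix(preds, ncol = length(models)))
}

#' Chronological train/test split with patient exclusivity
#'
#' Orders events by intubation date; the earliest ~`train_fraction` go to
#' training. A patient whose events straddle the cut follows the partition
#' of their earliest event, so no patient appears in both partitions.
#'
#' @param events event table with `event_id`, `patient_id`,
#'   `intubation_time`.
#' @param train_fraction fraction of events in training (default 0.75).
#' @return list with `train` and `test` event-id vectors.
#' @export
chronological_split <- function(events, train_fraction = 0.75) {
  if (nrow(events) < 2L) stop("need at least 2 events to split")
  ## order patients by their earliest intubation; accumulate whole patients
  ## (so a straddling patient follows their earliest event) until the event
  ## count reaches the training target -- the training share is then within
  ## one patient's events of the requested fraction
  first_time <- tapply(as.numeric(events$intubation_time), events$patient_id, min)
  pats <- names(sort(first_time))
  n_ev <- table(events$patient_id)[pats]
  cum <- cumsum(as.numeric(n_ev))
  target <- train_fraction * nrow(events)
  k <- max(1L, sum(cum <= target + 1e-9))
  k <- min(k, length(pats) - 1L)
  train_pats <- pats[seq_len(k)]
  in_train <- events$patient_id %in% as.integer(train_pats) |
    as.character(events$patient_id) %in% train_pats
  list(train = events$event_id[in_train], test = events$event_id[!in_train])
}
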