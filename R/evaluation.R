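#' Evaluation context
#'
#' Bundles everything imputation-error metrics need: the complete reference
#' table, per-variable standardization SDs computed once from it, the
#' amputation mask, and optional originally-missing flags.
#'
#' @param complete complete reference table (or lagged wide matrix).
#' @param mask logical matrix of evaluated (amputed) cells, columns named.
#' @param census the variable census (kinds for mask columns; lagged copies
#'   inherit their base variable's kind).
#' @param original_flags optional logical matrix flagging cells that were
#'   missing in the original data.
#' @return an object of class `gb_eval_context`.
#' @export
eval_context <- function(complete, mask, census = NULL, original_flags = NULL) {
  vars <- colnames(mask)
  stopifnot(all(vars %in% names(complete)))
  kinds <- vapply(vars, function(v) {
    base <- sub("_lag[0-9]+$", "", v)
    if (!is.null(census) && base %in% census$name) {
      k <- census_kind(census, base)
      if (k == "binary") "numeric" else k
    } else if (is.factor(complete[[v]])) "categorical" else "numeric"
  }, character(1))
  sds <- vapply(vars, function(v) {
    if (kinds[[v]] == "categorical") NA_real_ else stats::sd(as.numeric(complete[[v]]))
  }, numeric(1))
  zero <- !is.na(sds) & sds == 0
  if (any(zero)) {
    warning("zero-SD variables excluded from standardized MSE: ",
            paste(vars[zero], collapse = ", "))
    sds[zero] <- NA_real_
  }
  structure(list(complete = complete, mask = mask, kinds = kinds, sds = sds,
                 original_flags = original_flags),
            class = "gb_eval_context")
}

#' Standardized imputation mean squared error
#'
#' For each numeric-kind variable, the mean squared difference between the
#' imputed (for multiply imputed methods: averaged) and true values over that
#' variable's amputed cells, standardized by the variable's SD in the
#' complete dataset. The dataset-level MSE is the unweighted mean over
#' variables with at least one amputed cell.
#'
#' @param ctx an [eval_context()].
#' @param imputed completed table to score.
#' @param cells optional logical matrix restricting the evaluated cells
#'   (defaults to the context mask).
#' @return list with `overall` and `per_variable` (named numeric).
#' @export
imputation_mse <- function(ctx, imputed, cells = NULL) {
  mask <- cells %||% ctx$mask
  num <- names(ctx$kinds)[ctx$kinds == "numeric" & !is.na(ctx$sds)]
  per <- vapply(num, function(v) {
    idx <- mask[, v]
    if (!any(idx)) return(NA_real_)
    err <- (as.numeric(imputed[[v]][idx]) - as.numeric(ctx$complete[[v]][idx])) / ctx$sds[[v]]
    mean(err^2)
  }, numeric(1))
  if (all(is.na(per))) stop("no amputed numeric cells to evaluate")
  list(overall = mean(per, na.rm = TRUE), per_variable = per)
}

#' Classification error of categorical imputations
#'
#' Fraction of amputed categorical cells whose imputed level differs from
#' the true level, per variable, then averaged.
#'
#' @inheritParams imputation_mse
#' @return list with `overall` and `per_variable`.
#' @export
classification_error <- function(ctx, imputed, cells = NULL) {
  mask <- cells %||% ctx$mask
  cats <- names(ctx$kinds)[ctx$kinds == "categorical"]
  if (length(cats) == 0L) stop("no categorical variables in the mask")
  per <- vapply(cats, function(v) {
    idx <- mask[, v]
    if (!any(idx)) return(NA_real_)
    mean(as.character(imputed[[v]][idx]) != as.character(ctx$complete[[v]][idx]))
  }, numeric(1))
  if (all(is.na(per))) stop("no amputed categorical cells to evaluate")
  list(overall = mean(per, na.rm = TRUE), per_variable = per)
}

#' Prediction performance metrics
#'
#' Binary tasks: sensitivity, specificity, balanced accuracy
#' ((sens + spec) / 2), positive and negative predictive value, F1, accuracy
#' and AUC. Continuous tasks: MSE, RMSE, MAE and R-squared. AUC is reported
#' as NA when only one class is present.
#'
#' @param labels true labels (0/1 or numeric).
#' @param scores predicted probabilities or values.
#' @param task `"binary"` or `"continuous"`.
#' @param threshold classification threshold.
#' @return named numeric vector of metrics.
#' @export
prediction_metrics <- function(labels, scores, task = c("binary", "continuous"),
                               threshold = 0.5) {
  task <- match.arg(task)
  keep <- !is.na(labels) & !is.na(scores)
  labels <- labels[keep]; scores <- scores[keep]
  if (length(labels) == 0L) stop("no labeled rows to evaluate")
  if (task == "continuous") {
    err <- scores - labels
    mse <- mean(err^2)
    return(c(mse = mse, rmse = sqrt(mse), mae = mean(abs(err)),
             r2 = 1 - mse / mean((labels - mean(labels))^2)))
  }
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  f1 <- if (!is.na(ppv) && !is.na(sens) && ppv + sens > 0)
    2 * ppv * sens / (ppv + sens) else NA_real_
  auc <- if (length(unique(labels)) == 2L)
    as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  else NA_real_
  c(balanced_accuracy = (sens + spec) / 2, auc = auc,
    sensitivity = sens, specificity = spec, ppv = ppv, npv = npv, f1 = f1,
    accuracy = mean(pred == labels))
}

#' Variability across methods and train-test overfit gaps
#'
#' Coefficient of variation (sample SD / mean) of a metric across imputation
#' methods -- the axis the benchmark compares -- computed on per-method means
#' pooled over scenarios; and per-dataset train minus test gaps.
#'
#' @param report tidy evaluation report (columns `method`, `partition`,
#'   `metric`, `value`, plus scenario coordinates).
#' @param metric metric name to summarize.
#' @return list with `cv` (numeric scalar, NA when the mean is 0), and
#'   `overfit` (data frame of train - test gaps per dataset and method).
#' @export
variability_and_overfit <- function(report, metric) {
  rp <- report[report$metric == metric & report$partition == "test", ]
  per_method <- tapply(rp$value, rp$method, mean, na.rm = TRUE)
  mu <- mean(per_method)
  cv <- if (length(per_method) > 1 && is.finite(mu) && mu != 0)
    stats::sd(per_method) / mu else NA_real_

  keys <- c("mechanism", "level", "replicate", "method")
  keys <- intersect(keys, names(report))
  tr <- report[report$metric == metric & report$partition == "train", ]
  te <- report[report$metric == metric & report$partition == "test", ]
  gaps <- NULL
  if (nrow(tr) > 0 && nrow(te) > 0) {
    gaps <- merge(tr[, c(keys, "value")], te[, c(keys, "value")],
                  by = keys, suffixes = c("_train", "_test"))
    gaps$gap <- gaps$value_train - gaps$value_test
  }
  list(cv = cv, overfit = gaps)
}

#' Per-variable lag-1 autocorrelation
#'
#' Pooled within-event lag-1 Pearson correlation: consecutive-window pairs
#' are collected across events (event-boundary pairs dropped) and correlated.
#'
#' @param wt window table (or any table with `event_id`, `window_index` and
#'   the variables).
#' @param vars variables to estimate (default: numeric columns).
#' @return named numeric vector of AR(1) estimates (NA for constants).
#' @export
ar1_by_variable <- function(wt, vars = NULL) {
  ord <- order(wt$event_id, wt$window_index)
  wt <- wt[ord, , drop = FALSE]
  if (is.null(vars))
    vars <- setdiff(names(wt)[vapply(wt, is.numeric, logical(1))],
                    c(ID_COLS, grep("^label_", names(wt), value = TRUE)))
  n <- nrow(wt)
  valid_pair <- wt$event_id[-n] == wt$event_id[-1] &
    wt$window_index[-1] == wt$window_index[-n] + 1L
  vapply(vars, function(v) {
    x <- as.numeric(wt[[v]])
    x0 <- x[-n][valid_pair]
    x1 <- x[-1][valid_pair]
    ok <- !is.na(x0) & !is.na(x1)
    if (sum(ok) < 3 || stats::sd(x0[ok]) == 0 || stats::sd(x1[ok]) == 0)
      return(NA_real_)
    stats::cor(x0[ok], x1[ok])
  }, numeric(1))
}

#' Correlation between temporal autocorrelation and imputation error
#'
#' Pearson correlation, across variables, of each variable's AR(1)
#' coefficient with its per-variable imputation error under a method. A
#' strongly negative correlation indicates the method exploits temporal
#' stability (the signature of carry-forward imputation).
#'
#' @param ar1 named AR(1) vector from [ar1_by_variable()].
#' @param per_variable_error named per-variable error vector (e.g. from
#'   [imputation_mse()]).
#' @return Pearson r (numeric scalar).
#' @export
autocorrelation_error_cor <- function(ar1, per_variable_error) {
  common <- intersect(names(ar1), names(per_variable_error))
  a <- ar1[common]; e <- per_variable_error[common]
  ok <- !is.na(a) & !is.na(e)
  if (sum(ok) < 3) return(NA_real_)
  stats::cor(a[ok], e[ok])
}

#' Stratify imputation error by original missingness
#'
#' Reports error metrics separately for cells that were missing in the
#' original data (and filled to build the synthetic complete table) versus
#' cells originally observed. The strata partition the evaluated cells, and
#' per-stratum MSEs recombine to the pooled value as a variable-count
#' weighted mean.
#'
#' @param ctx an [eval_context()] with `original_flags`.
#' @param imputed completed table to score.
#' @return data frame with one row per stratum x metric.
#' @export
stratify_by_original_missingness <- function(ctx, imputed) {
  if (is.null(ctx$original_flags)) {
    message("originally-missing flags absent; single stratum reported")
    mse <- imputation_mse(ctx, imputed)
    return(data.frame(stratum = "all", metric = "mse", value = mse$overall))
  }
  flags <- ctx$original_flags[, colnames(ctx$mask), drop = FALSE]
  out <- list()
  for (stratum in c("originally_missing", "originally_observed")) {
    cells <- if (stratum == "originally_missing") ctx$mask & flags else ctx$mask & !flags
    if (!any(cells)) next
    num_ok <- any(cells[, names(ctx$kinds)[ctx$kinds == "numeric"], drop = FALSE])
    if (num_ok) {
      mse <- imputation_mse(ctx, imputed, cells = cells)
      out[[length(out) + 1L]] <- data.frame(stratum = stratum, metric = "mse",
                                            value = mse$overall)
    }
  }
  do.call(rbind, out)
}
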