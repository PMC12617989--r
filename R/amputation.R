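#' Missingness scenario
#'
#' Describes one cell of the mechanism x proportion grid. Mechanisms follow
#' the multivariate-amputation scheme: rows are assigned to patterns (one per
#' variable group), a weighted sum of standardized values scores each row,
#' and a shifted-logistic allocation converts scores to per-row missingness
#' probabilities calibrated so the expected cell-wise missing proportion
#' equals `level * base_cell_proportion`.
#'
#' Weight policies per mechanism (weights uniform within a class):
#' \itemize{
#'   \item MCAR: no weights; every row equally likely.
#'   \item MAR: unit weight on variables observed under the pattern, plus the
#'     outcome; zero on the to-be-amputed variables.
#'   \item MNAR_weak: observed:amputed weight ratio 2:1 (plus outcome).
#'   \item MNAR_moderate: ratio 1:1 (plus outcome).
#'   \item MNAR_strong: missingness driven solely by the to-be-amputed
#'     variables (ratio 0:1, plus outcome).
#' }
#'
#' @param mechanism one of `"MCAR"`, `"MAR"`, `"MNAR_weak"`,
#'   `"MNAR_moderate"`, `"MNAR_strong"`.
#' @param level proportion multiplier (the full benchmark grid uses 0.5, 1, 2).
#' @param base_cell_proportion base cell-wise missing proportion
#'   (default 0.182, the original-data fraction).
#' @param include_outcome whether the outcome joins the weighted sum
#'   (default: yes for every mechanism except MCAR).
#' @param seed integer seed for pattern assignment and Bernoulli draws.
#' @return an object of class `gb_scenario`.
#' @export
missingness_scenario <- function(mechanism = c("MCAR", "MAR", "MNAR_weak",
                                               "MNAR_moderate", "MNAR_strong"),
                                 level = 1,
                                 base_cell_proportion = 0.182,
                                 include_outcome = NULL,
                                 seed = 1L) {
  mechanism <- match.arg(mechanism)
  if (level < 0) stop("level must be nonnegative")
  if (base_cell_proportion < 0 || base_cell_proportion >= 1)
    stop("base_cell_proportion must lie in [0, 1)")
  structure(list(mechanism = mechanism, level = level,
                 base_cell_proportion = base_cell_proportion,
                 include_outcome = include_outcome %||% (mechanism != "MCAR"),
                 seed = as.integer(seed)),
            class = "gb_scenario")
}

## observed:amputed weight ratios per mechanism
mechanism_weights <- function(mechanism) {
  switch(mechanism,
         MCAR = c(observed = 0, amputed = 0),
         MAR = c(observed = 1, amputed = 0),
         MNAR_weak = c(observed = 2, amputed = 1),
         MNAR_moderate = c(observed = 1, amputed = 1),
         MNAR_strong = c(observed = 0, amputed = 1))
}

#' Build missingness patterns from the census
#'
#' One pattern per variable group (1-5); a pattern's amputed set is the
#' group's amputable variables. Variables with no group are never amputed.
#'
#' @param census the variable census.
#' @return named list of character vectors (amputed variables per pattern).
#' @export
build_patterns <- function(census) {
  amp <- census[census$amputable, , drop = FALSE]
  groups <- sort(unique(amp$group))
  pats <- lapply(groups, function(g) amp$name[amp$group == g])
  if (any(lengths(pats) == 0L)) stop("empty variable group")
  names(pats) <- paste0("group", groups)
  pats
}

#' Weighted-sum scores for a pattern
#'
#' Scores each row as the weighted sum of standardized (z-scored, using the
#' table's own mean/SD) numeric-kind variables, with weights determined by
#' the mechanism's observed/amputed class ratio, plus the outcome when
#' included. MCAR yields constant zero scores. Zero-variance variables are
#' dropped from the sum with a warning; categorical variables do not enter
#' the score.
#'
#' @param data complete table (predictor columns).
#' @param pattern character vector of to-be-amputed variables.
#' @param mechanism mechanism name.
#' @param amputable character vector of all amputable variables (the
#'   "observed" class under this pattern is the amputable complement plus the
#'   never-amputed numeric predictors).
#' @param outcome optional numeric outcome vector entering with unit weight.
#' @param kinds named kind vector for the score-eligible columns.
#' @return numeric score per row.
#' @export
weighted_sum_scores <- function(data, pattern, mechanism, amputable,
                                outcome = NULL, kinds = NULL) {
  n <- nrow(data)
  w <- mechanism_weights(mechanism)
  score <- numeric(n)
  if (all(w == 0) && is.null(outcome)) return(score)
  if (is.null(kinds))
    kinds <- vapply(data, function(c) if (is.factor(c)) "categorical" else "numeric",
                    character(1))
  eligible <- names(kinds)[kinds != "categorical"]
  for (v in eligible) {
    wv <- if (v %in% pattern) w[["amputed"]] else w[["observed"]]
    if (wv == 0) next
    x <- data[[v]]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      warning(sprintf("zero-variance variable '%s' dropped from missingness score", v))
      next
    }
    score <- score + wv * (x - mean(x)) / s
  }
  if (!is.null(outcome) && mechanism != "MCAR") {
    s <- stats::sd(outcome)
    if (is.finite(s) && s > 0) score <- score + (outcome - mean(outcome)) / s
  }
  score
}

#' Calibrate per-row missingness probabilities
#'
#' Solves, by bisection, for the offset c such that
#' mean(plogis(score + c)) equals the target row probability; probabilities
#' are monotone increasing in the score.
#'
#' @param scores finite numeric scores.
#' @param target_row_prob target mean probability in [0, 1).
#' @param tol tolerance on the mean probability.
#' @return numeric vector of probabilities.
#' @export
calibrate_probability <- function(scores, target_row_prob, tol = 1e-9) {
  if (!all(is.finite(scores))) stop("scores must be finite")
  if (target_row_prob < 0 || target_row_prob >= 1)
    stop("target_row_prob must lie in [0, 1)")
  if (target_row_prob == 0) return(rep(0, length(scores)))
  f <- function(c0) mean(stats::plogis(scores + c0)) - target_row_prob
  r <- max(abs(scores))
  lo <- stats::qlogis(target_row_prob) - r - 1
  hi <- stats::qlogis(target_row_prob) + r + 1
  c0 <- stats::uniroot(f, c(lo, hi), tol = tol)$root
  stats::plogis(scores + c0)
}

#' Ampute a complete table under a missingness scenario
#'
#' Every pattern is applied independently to every row: the row is scored by
#' the pattern's weighted sum, the shifted-logistic allocation converts the
#' scores to probabilities, and on a positive Bernoulli draw the pattern's
#' amputed cells in that row become missing (so a row may receive several
#' patterns' gaps, as windowed EHR rows do). The common target row
#' probability is derived from the pattern sizes so the expected cell-wise
#' missing proportion -- over all predictor cells of the table -- equals
#' `level * base_cell_proportion`.
#'
#' @param complete complete window table (data.frame; id/label columns are
#'   passed through untouched).
#' @param scenario a [missingness_scenario()].
#' @param census the variable census.
#' @param outcome optional numeric outcome vector (length nrow) entering the
#'   scores for MAR/MNAR mechanisms.
#' @return list: `data` (amputed table), `mask` (logical matrix over
#'   predictor columns, TRUE = rendered missing), `pattern_hits` (logical
#'   row x pattern matrix), `achieved_cell_proportion` (missing cells / all
#'   predictor cells), `scenario`.
#' @export
ampute <- function(complete, scenario, census, outcome = NULL) {
  stopifnot(inherits(scenario, "gb_scenario"))
  pred <- census_predictors(census)
  pred <- pred[pred %in% names(complete)]
  if (anyNA(complete[pred])) stop("ampute requires a complete table")
  patterns <- build_patterns(census)
  patterns <- lapply(patterns, intersect, y = pred)
  patterns <- patterns[lengths(patterns) > 0]
  n <- nrow(complete)
  n_cols <- length(pred)
  target_cell <- scenario$level * scenario$base_cell_proportion

  mask <- matrix(FALSE, n, n_cols, dimnames = list(NULL, pred))
  G <- length(patterns)
  hits <- matrix(FALSE, n, G, dimnames = list(NULL, names(patterns)))
  if (target_cell == 0) {
    return(list(data = complete, mask = mask, pattern_hits = hits,
                achieved_cell_proportion = 0, scenario = scenario))
  }

  set.seed(scenario$seed)
  sizes <- lengths(patterns)

  ## expected missing cells = p * sum(sizes) per row, hence
  ## p = target_cell * n_cols / sum(sizes); attainable iff the target does
  ## not exceed the amputable-cell fraction
  p_row <- target_cell * n_cols / sum(sizes)
  if (p_row > 1)
    stop(sprintf(
      "requested cell proportion %.3f unattainable: amputable fraction is %.3f",
      target_cell, sum(sizes) / n_cols))

  kinds <- stats::setNames(census_kind(census, pred), pred)
  out_vec <- if (scenario$include_outcome) outcome else NULL
  for (g in seq_len(G)) {
    scores <- if (scenario$mechanism == "MCAR") numeric(n) else
      weighted_sum_scores(complete[pred], patterns[[g]],
                          scenario$mechanism, census_amputable(census),
                          outcome = out_vec, kinds = kinds)
    probs <- calibrate_probability(scores, p_row)
    hit <- stats::runif(n) < probs
    hits[, g] <- hit
    if (any(hit)) mask[hit, patterns[[g]]] <- TRUE
  }
  data <- complete
  for (v in pred) {
    idx <- mask[, v]
    if (any(idx)) data[[v]][idx] <- NA
  }
  list(data = data, mask = mask, pattern_hits = hits,
       achieved_cell_proportion = mean(mask), scenario = scenario)
}

#' Propagate a base-window mask onto the lagged wide matrix
#'
#' Amputation precedes lag construction: a lagged feature is missing exactly
#' when its base window's cell is missing. Given the base mask (aligned to
#' the window table) this returns the mask over the wide matrix's feature
#' columns for the wide matrix's rows.
#'
#' @param mask base logical mask (rows of the window table).
#' @param wt the window table the mask aligns to.
#' @param wide the lagged wide matrix from [build_lagged_matrix()].
#' @param spec the [window_spec()].
#' @return logical matrix aligned to `wide`'s feature columns.
#' @export
lag_mask <- function(mask, wt, wide, spec = window_spec()) {
  key_wt <- paste(wt$event_id, wt$window_index)
  feature_cols <- attr(wide, "feature_cols")
  out <- matrix(FALSE, nrow(wide), length(feature_cols),
                dimnames = list(NULL, feature_cols))
  base_vars <- intersect(colnames(mask), feature_cols)
  idx0 <- match(paste(wide$event_id, wide$window_index), key_wt)
  out[, base_vars] <- mask[idx0, base_vars]
  lagged <- grep("_lag[0-9]+$", feature_cols, value = TRUE)
  for (col in lagged) {
    l <- as.integer(sub("^.*_lag", "", col))
    base <- sub("_lag[0-9]+$", "", col)
    if (!base %in% colnames(mask)) next
    idx <- match(paste(wide$event_id, wide$window_index - l), key_wt)
    out[, col] <- mask[idx, base]
    out[is.na(idx), col] <- FALSE
  }
  out
}

#' Serialize a mask as a sparse (row, column) CSV plus metadata JSON
#'
#' @param amp result of [ampute()].
#' @param path CSV path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(amp, path) {
  idx <- which(amp$mask, arr.ind = TRUE)
  data.table::fwrite(data.table::data.table(
    row = idx[, 1], column = colnames(amp$mask)[idx[, 2]]), path)
  meta <- list(mechanism = amp$scenario$mechanism, level = amp$scenario$level,
               base_cell_proportion = amp$scenario$base_cell_proportion,
               seed = amp$scenario$seed,
               achieved_cell_proportion = amp$achieved_cell_proportion,
               n_rows = nrow(amp$mask), columns = colnames(amp$mask))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
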