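#' Linear interpolation of interior gaps
#'
#' Interpolates interior missing values of a numeric within-event series
#' linearly on the window index; leading and trailing gaps are untouched.
#'
#' @param x numeric series (one event, windows in order).
#' @return the series with interior gaps filled.
#' @export
interpolate_linear <- function(x) {
  if (!is.numeric(x)) stop("interpolate_linear requires a numeric series")
  if (sum(!is.na(x)) < 2L) return(x)
  as.numeric(zoo::na.approx(x, x = seq_along(x), na.rm = FALSE))
}

#' Nearest-neighbor fill
#'
#' Fills remaining gaps (leading/trailing, or any gap for categorical
#' series) with the nearest observed value; equidistant neighbors resolve to
#' the earlier one.
#'
#' @param x vector (numeric or factor), one event's series.
#' @return the series with gaps filled where any observed value exists.
#' @export
nearest_fill <- function(x) {
  obs <- which(!is.na(x))
  if (length(obs) == 0L || length(obs) == length(x)) return(x)
  for (i in which(is.na(x))) {
    d <- abs(obs - i)
    ## ties broken toward the earlier observation: which.min picks the first
    x[i] <- x[obs[which.min(d)]]
  }
  x
}

#' Default deterministic fallback formulas
#'
#' Registry of clinical fallback rules for variables that may be entirely
#' unobserved in an event. The default carries the standard pediatric
#' endotracheal-tube sizing formula, ETT size = age in years / 4 + 4.
#'
#' @return named list of functions taking the window table and returning the
#'   variable's value per row.
#' @export
default_formula_rules <- function() {
  list(ett_size = function(df) {
    if (!"age_years" %in% names(df) || anyNA(df$age_years))
      stop("ett_size rule requires a complete age_years column")
    df$age_years / 4 + 4
  })
}

#' Apply formula fallbacks
#'
#' Fills cells that remain missing after interpolation and nearest fill and
#' that are covered by a deterministic rule.
#'
#' @param table window table.
#' @param rules registry from [default_formula_rules()].
#' @return list with the table and a logical matrix of filled cells.
#' @export
formula_fallback <- function(table, rules = default_formula_rules()) {
  filled <- matrix(FALSE, nrow(table), length(rules),
                   dimnames = list(NULL, names(rules)))
  for (v in intersect(names(rules), names(table))) {
    idx <- is.na(table[[v]])
    if (any(idx)) {
      vals <- rules[[v]](table)
      table[[v]][idx] <- vals[idx]
      filled[idx, v] <- TRUE
    }
  }
  list(table = table, filled = filled)
}

#' Construct a fully observed window table
#'
#' Builds the "synthetic complete" reference table from a gappy window table
#' by a fixed pipeline: (1) linear interpolation of interior numeric gaps on
#' the window index; (2) nearest-observed fill of remaining gaps within each
#' event (categorical series skip interpolation and go straight here);
#' (3) deterministic formula fallbacks for never-observed variables covered
#' by a rule; (4) random-forest donor imputation (self-fit on the table
#' itself) for whatever remains. Observed cells are never altered; each step
#' weakly reduces the missing-cell count, and the output has none.
#'
#' @param wt window table with gaps (id columns + census variables).
#' @param census the variable census.
#' @param rules formula registry, see [default_formula_rules()].
#' @param seed seed for the model-based final step.
#' @param rf_spec optional [imputer_spec()] overriding the model-fallback
#'   controls (method is forced to `"rf_donor"`).
#' @return list with `table` (complete window table) and `provenance`
#'   (integer matrix over predictor/outcome columns: 0 observed,
#'   1 interpolated, 2 nearest, 3 formula, 4 model).
#' @export
complete_table <- function(wt, census, rules = default_formula_rules(),
                           seed = 1L, rf_spec = NULL) {
  vars <- census$name[census$name %in% names(wt)]
  kinds <- stats::setNames(census_kind(census, vars), vars)
  prov <- matrix(0L, nrow(wt), length(vars), dimnames = list(NULL, vars))
  ord <- order(wt$event_id, wt$window_index)
  if (any(ord != seq_along(ord))) wt <- wt[ord, , drop = FALSE]

  ev_split <- split(seq_len(nrow(wt)), wt$event_id)
  for (v in vars) {
    col <- wt[[v]]
    for (rows in ev_split) {
      x <- col[rows]
      na0 <- is.na(x)
      if (!any(na0)) next
      if (kinds[[v]] %in% c("numeric", "binary")) {
        x1 <- interpolate_linear(x)
        prov[rows[na0 & !is.na(x1)], v] <- 1L
      } else x1 <- x
      x2 <- nearest_fill(x1)
      prov[rows[is.na(x1) & !is.na(x2)], v] <- 2L
      col[rows] <- x2
    }
    wt[[v]] <- col
  }

  fb <- formula_fallback(wt, rules)
  wt <- fb$table
  for (v in intersect(colnames(fb$filled), vars)) prov[fb$filled[, v], v] <- 3L

  still <- vapply(wt[vars], function(c) sum(is.na(c)), integer(1))
  if (any(still > 0)) {
    never <- names(still)[vapply(wt[vars], function(c) all(is.na(c)), logical(1))]
    if (length(never) > 0)
      stop("variables with zero observed values and no rule: ",
           paste(never, collapse = ", "))
    spec <- rf_spec %||% imputer_spec("rf_donor", m = 1L, n_trees = 50L,
                                      chained_iters = 2L)
    spec$method <- "rf_donor"
    spec$m <- 1L
    spec$seed <- seed
    fit <- fit_imputer(spec, wt[, c("event_id", "window_index", vars)],
                       census = census)
    bundle <- apply_imputer(fit, wt[, c("event_id", "window_index", vars)])
    filled <- bundle$average
    for (v in vars) {
      idx <- is.na(wt[[v]])
      if (any(idx)) {
        wt[[v]][idx] <- filled[[v]][idx]
        prov[idx, v] <- 4L
      }
    }
  }
  stopifnot(!anyNA(wt[vars]))
  list(table = wt, provenance = prov)
}
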