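#' Variable census
#'
#' A variable census describes every column of the windowed modeling table:
#' its kind (numeric, binary, categorical), whether it is static within an
#' intubation event, whether the amputation stage may render it missing, which
#' missingness pattern group it belongs to, and the parameters of its
#' generating process (lag-1 autocorrelation `rho`, loading on the shared
#' latent severity process, raw observation cadence).
#'
#' @param n_numeric_tv number of amputable continuous time-varying variables.
#' @param n_binary_tv number of amputable binary time-varying variables
#'   (a "select all that apply" indicator block, pattern group 4).
#' @param n_categorical_tv number of amputable multi-level categorical
#'   time-varying variables.
#' @param n_levels integer vector of level counts for the categorical
#'   variables (recycled).
#' @param n_numeric_tv_fixed number of never-missing numeric time-varying
#'   variables (e.g. pulse; observed essentially always).
#' @param n_binary_tv_fixed number of never-missing binary time-varying
#'   variables.
#' @param n_static_amputable number of amputable numeric static variables.
#'   The first is `weight_kg`; the second, when present, is `ett_size`,
#'   which carries a deterministic formula fallback (age/4 + 4).
#' @param n_static_fixed number of never-missing static variables in addition
#'   to `age_years` and `sex` (which are always present).
#' @param ar1_range interval from which per-variable lag-1 autocorrelation
#'   coefficients are spread (evenly spaced, deterministic).
#' @param loading_range interval over which loadings on the latent severity
#'   process are spread.
#' @param cadence_hours candidate raw-observation cadences (hours between
#'   observations), assigned cyclically to time-varying variables.
#'
#' @return A `data.frame` with one row per variable and columns
#'   `name`, `kind`, `n_levels`, `static`, `amputable`, `group`,
#'   `select_all_block`, `role`, `rho`, `loading`, `cadence_hours`.
#' @export
make_census <- function(n_numeric_tv = 46,
                        n_binary_tv = 12,
                        n_categorical_tv = 2,
                        n_levels = c(6L, 4L),
                        n_numeric_tv_fixed = 21,
                        n_binary_tv_fixed = 2,
                        n_static_amputable = 2,
                        n_static_fixed = 12,
                        ar1_range = c(0.2, 0.95),
                        loading_range = c(0.2, 0.7),
                        cadence_hours = c(1, 2, 4)) {
  stopifnot(n_numeric_tv >= 1, ar1_range[1] >= 0, ar1_range[2] < 1)
  pad <- function(prefix, n) sprintf("%s_%02d", prefix, seq_len(n))

  rec <- function(name, kind, n_lev, static, amputable, role = "predictor") {
    if (length(name) == 0L) return(NULL)
    data.frame(name = name, kind = kind, n_levels = n_lev, static = static,
               amputable = amputable, role = role, stringsAsFactors = FALSE)
  }

  cen <- rbind(
    rec(pad("vital", n_numeric_tv), "numeric", NA_integer_, FALSE, TRUE),
    rec(pad("assess_flag", n_binary_tv), "binary", 2L, FALSE, TRUE),
    rec(if (n_categorical_tv > 0) pad("scale", n_categorical_tv) else character(),
        "categorical", rep_len(as.integer(n_levels), max(n_categorical_tv, 1L))[seq_len(n_categorical_tv)],
        FALSE, TRUE),
    rec(pad("monitor", n_numeric_tv_fixed), "numeric", NA_integer_, FALSE, FALSE),
    rec(pad("device_flag", n_binary_tv_fixed), "binary", 2L, FALSE, FALSE),
    rec(c("weight_kg", "ett_size")[seq_len(min(n_static_amputable, 2L))],
        "numeric", NA_integer_, TRUE, TRUE),
    rec(c("age_years"), "numeric", NA_integer_, TRUE, FALSE),
    rec(c("sex"), "binary", 2L, TRUE, FALSE),
    rec(if (n_static_fixed > 0) pad("baseline", n_static_fixed) else character(),
        "numeric", NA_integer_, TRUE, FALSE),
    rec("bp_percentile", "numeric", NA_integer_, FALSE, FALSE, role = "outcome")
  )
  rownames(cen) <- NULL

  ## Pattern groups over amputable variables: the binary indicator block is
  ## group 4 ("select all that apply"); remaining amputable variables are
  ## dealt round-robin into groups 1, 2, 3, 5.
  cen$group <- NA_integer_
  cen$select_all_block <- NA_integer_
  amp <- which(cen$amputable)
  blk <- which(cen$amputable & cen$kind == "binary" & !cen$static)
  cen$group[blk] <- 4L
  cen$select_all_block[blk] <- 1L
  rest <- setdiff(amp, blk)
  cen$group[rest] <- rep_len(c(1L, 2L, 3L, 5L), length(rest))

  ## Generating-process parameters: rho spread evenly over ar1_range across
  ## time-varying predictors (deterministic, so parameter-recovery checks have
  ## known truth); loadings interleaved over loading_range; statics constant.
  tv <- which(!cen$static & cen$role == "predictor")
  n_tv <- length(tv)
  cen$rho <- 0
  cen$rho[tv] <- if (n_tv == 1L) mean(ar1_range) else
    seq(ar1_range[1], ar1_range[2], length.out = n_tv)
  cen$loading <- 0
  ## loadings run opposite to rho so autocorrelation and cross-correlation
  ## strength are not confounded across variables
  cen$loading[tv] <- if (n_tv == 1L) mean(loading_range) else
    seq(loading_range[2], loading_range[1], length.out = n_tv)
  cen$cadence_hours <- NA_real_
  cen$cadence_hours[tv] <- rep_len(cadence_hours, n_tv)
  out <- which(cen$role == "outcome")
  cen$rho[out] <- 0.9
  cen$loading[out] <- 0
  cen$cadence_hours[out] <- 1

  class(cen) <- c("gb_census", "data.frame")
  cen
}

#' Default variable census
#'
#' The default census has 99 predictor variables, 83 of them time-varying, so
#' that the lagged wide matrix has 83 * 3 + 16 = 265 feature columns, of which
#' 176 numeric-kind and 6 categorical features are subject to amputation.
#'
#' @return a `gb_census` data frame (see [make_census()]).
#' @export
default_census <- function() make_census()

#' @export
print.gb_census <- function(x, ...) {
  cat(sprintf(
    "Variable census: %d predictors (%d time-varying, %d static), %d amputable; %d outcome series\n",
    sum(x$role == "predictor"), sum(x$role == "predictor" & !x$static),
    sum(x$role == "predictor" & x$static), sum(x$amputable),
    sum(x$role == "outcome")))
  invisible(x)
}

census_predictors <- function(census) census$name[census$role == "predictor"]

census_amputable <- function(census) census$name[census$amputable]

census_kind <- function(census, names) {
  census$kind[match(names, census$name)]
}

#' Write / read a census sidecar
#'
#' @param census a `gb_census`.
#' @param path file path for the JSON sidecar.
#' @return `read_census` returns the census; `write_census` returns `path`
#'   invisibly.
#' @export
write_census <- function(census, path) {
  jsonlite::write_json(as.data.frame(census), path, dataframe = "columns",
                       auto_unbox = FALSE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_census
#' @export
read_census <- function(path) {
  cen <- as.data.frame(jsonlite::fromJSON(path))
  int_cols <- c("n_levels", "group", "select_all_block")
  for (cc in intersect(int_cols, names(cen))) cen[[cc]] <- as.integer(cen[[cc]])
  class(cen) <- c("gb_census", "data.frame")
  cen
}
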