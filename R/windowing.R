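#' Window specification
#'
#' Defines the 4-hour aggregation grid, eligibility rules, lag depth, and
#' label leads of the modeling table. Window k of an event covers the
#' half-open interval (intubation + width*(k-1), intubation + width*k] hours.
#' The first L windows of each event exist only to supply lagged features; the
#' first window eligible as a modeling row is window L + 1, whose end lies
#' width * (L + 1) hours after intubation (12 h with the defaults).
#'
#' @param width_hours window width in hours.
#' @param min_duration_hours events intubated for no more than this many hours
#'   are excluded (strict inequality: exactly 24 h is excluded).
#' @param n_lags number of lagged windows appended as features (L).
#' @param binary_label_lead lead of the binary extubation label, in windows.
#' @param continuous_label_lead lead of the continuous blood-pressure label,
#'   in windows.
#' @param age_bounds_years events with ages outside (lower, upper) are
#'   excluded when an age column is present; lower bound 30 days.
#' @return an object of class `gb_window_spec`.
#' @export
window_spec <- function(width_hours = 4,
                        min_duration_hours = 24,
                        n_lags = 2L,
                        binary_label_lead = 3L,
                        continuous_label_lead = 1L,
                        age_bounds_years = c(30 / 365.25, 18)) {
  stopifnot(width_hours > 0, n_lags >= 0,
            binary_label_lead >= 1, continuous_label_lead >= 1)
  structure(list(width_hours = width_hours,
                 min_duration_hours = min_duration_hours,
                 n_lags = as.integer(n_lags),
                 first_model_window_end = width_hours * (n_lags + 1),
                 binary_label_lead = as.integer(binary_label_lead),
                 continuous_label_lead = as.integer(continuous_label_lead),
                 age_bounds_years = age_bounds_years),
            class = "gb_window_spec")
}

#' Filter events by eligibility rules
#'
#' Removes events intubated for `min_duration_hours` or less (such events are
#' typically procedural intubations) and, when an `age_years` column is
#' available, events outside the age bounds.
#'
#' @param events event table with `duration_hours` (or `intubation_time` /
#'   `extubation_time`), optionally `age_years`.
#' @param spec a [window_spec()].
#' @return the filtered event table.
#' @export
filter_eligible_events <- function(events, spec = window_spec()) {
  if (nrow(events) == 0L) return(events)
  dur <- if ("duration_hours" %in% names(events)) events$duration_hours else
    as.numeric(difftime(events$extubation_time, events$intubation_time, units = "hours"))
  keep <- dur > spec$min_duration_hours
  if ("age_years" %in% names(events)) {
    keep <- keep & events$age_years > spec$age_bounds_years[1] &
      events$age_years < spec$age_bounds_years[2]
  }
  events[keep, , drop = FALSE]
}

#' Collapse raw observations into the window grid
#'
#' Numeric and binary cells take the mean of in-window observations;
#' categorical cells take the mode, with ties broken by the most recent
#' observation among the tied levels. A cell is missing iff no observation
#' fell in the window. Observations outside any window (at or before
#' intubation, or after the last window's end) are dropped with a warning
#' giving their count.
#'
#' @param cohort a `gb_raw_cohort` from [generate_cohort()], or a list with
#'   `observations`, `events`, `census`.
#' @param spec a [window_spec()].
#' @return a `gb_window_table`: data.frame keyed by (event_id, window_index),
#'   one column per census variable (categorical as factor), plus
#'   `patient_id`, `n_windows`, and an `eligible` flag
#'   (window_index > n_lags).
#' @export
collapse_to_windows <- function(cohort, spec = window_spec()) {
  obs <- data.table::as.data.table(cohort$observations)
  events <- cohort$events
  cen <- cohort$census
  wh <- spec$width_hours

  ev <- data.table::as.data.table(events[, c("event_id", "patient_id",
                                             "intubation_time", "n_windows")])
  obs <- merge(obs, ev, by = c("event_id", "patient_id"), sort = FALSE)
  hrs <- as.numeric(difftime(obs$timestamp, obs$intubation_time, units = "hours"))
  obs[, window_index := as.integer(ceiling(hrs / wh))]
  bad <- obs$window_index < 1L | obs$window_index > obs$n_windows
  if (any(bad)) {
    warning(sprintf("%d observation(s) outside any window were dropped", sum(bad)))
    obs <- obs[!bad]
  }

  kinds <- stats::setNames(cen$kind, cen$name)
  obs[, kind := kinds[variable]]
  data.table::setorder(obs, event_id, variable, timestamp)

  num <- obs[kind != "categorical",
             .(value = mean(value)),
             by = .(event_id, window_index, variable)]
  cat_mode <- obs[kind == "categorical",
                  mode_latest(value),
                  by = .(event_id, window_index, variable)]
  cells <- rbind(num, cat_mode)

  wide <- data.table::dcast(cells, event_id + window_index ~ variable,
                            value.var = "value")

  ## full grid: every event x window 1..n_windows, even all-missing windows
  grid <- data.table::data.table(
    event_id = rep(events$event_id, events$n_windows),
    patient_id = rep(events$patient_id, events$n_windows),
    n_windows = rep(events$n_windows, events$n_windows),
    window_index = unlist(lapply(events$n_windows, seq_len)))
  wt <- merge(grid, wide, by = c("event_id", "window_index"),
              all.x = TRUE, sort = FALSE)
  data.table::setorder(wt, event_id, window_index)

  missing_cols <- setdiff(cen$name, names(wt))
  for (nm in missing_cols) wt[, (nm) := NA_real_]
  for (nm in cen$name[cen$kind == "categorical"]) {
    lev <- seq_len(cen$n_levels[cen$name == nm])
    wt[, (nm) := factor(as.integer(get(nm)), levels = lev)]
  }
  wt[, eligible := window_index > spec$n_lags]
  data.table::setcolorder(wt, c("event_id", "patient_id", "window_index",
                                "n_windows", "eligible", cen$name))
  out <- as.data.frame(wt)
  attr(out, "window_spec") <- spec
  class(out) <- c("gb_window_table", "data.frame")
  out
}

## mode with ties broken toward the most recently observed tied level;
## input values arrive in timestamp order
mode_latest <- function(v) {
  if (length(v) == 0L) return(list(value = numeric(0)))
  tab <- table(v)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1L) {
    latest <- v[max(which(as.character(v) %in% top))]
    top <- as.character(latest)
  }
  list(value = as.numeric(top))
}

#' Assign outcome labels to window rows
#'
#' The binary label of window k is 1 iff the event ends in successful
#' extubation and the extubation occurs by the end of window
#' k + `binary_label_lead`; an event still intubated at the horizon, or one
#' that terminates unsuccessfully, yields 0. The continuous label of window k
#' is the blood-pressure percentile observed at window
#' k + `continuous_label_lead` (NA when that window lies beyond the event).
#'
#' @param wt a `gb_window_table`.
#' @param events the event table with `n_windows`, `success`.
#' @param spec a [window_spec()].
#' @param bp_var name of the continuous outcome series column.
#' @return `wt` with `label_success` and `label_bp` columns.
#' @export
assign_labels <- function(wt, events, spec = window_spec(),
                          bp_var = "bp_percentile") {
  if (!all(c("success") %in% names(events))) stop("events must carry outcomes")
  idx <- match(wt$event_id, events$event_id)
  if (anyNA(idx)) stop("window rows reference unknown events")
  K <- events$n_windows[idx]
  horizon <- wt$window_index + spec$binary_label_lead
  ## extubation happens at the end of window K (within it); by the end of
  ## window k+lead the event has terminated iff k+lead >= K
  wt$label_success <- as.integer(horizon >= K & events$success[idx] == 1L)
  if (bp_var %in% names(wt)) {
    dt <- data.table::as.data.table(wt[, c("event_id", "window_index", bp_var)])
    tgt <- data.table::data.table(event_id = wt$event_id,
                                  window_index = wt$window_index + spec$continuous_label_lead)
    lab <- merge(tgt, dt, by = c("event_id", "window_index"),
                 all.x = TRUE, sort = FALSE)
    wt$label_bp <- lab[[bp_var]]
  }
  wt
}

#' Build the lagged wide modeling matrix
#'
#' For each time-varying variable v, appends columns `v_lag1` ... `v_lagL`
#' holding the value of v in the preceding windows of the same event; static
#' variables appear once. Only eligible rows (window_index > L) are kept, so
#' lag-support windows never appear as modeling rows. Lagged cells inherit
#' the base window's value, hence its missingness (and, downstream, its
#' imputed status). With the default census (99 variables, 83 time-varying,
#' L = 2) the matrix has 265 feature columns.
#'
#' @param wt a `gb_window_table` (labels optional, carried through).
#' @param spec a [window_spec()].
#' @param census the variable census.
#' @return a data.frame of eligible rows: id columns, feature columns, and any
#'   label columns. Attribute `feature_cols` lists the feature columns.
#' @export
build_lagged_matrix <- function(wt, spec = window_spec(), census) {
  dt <- data.table::as.data.table(wt)
  data.table::setorder(dt, event_id, window_index)
  pred <- census[census$role == "predictor", , drop = FALSE]
  tv <- pred$name[!pred$static]
  st <- pred$name[pred$static]
  L <- spec$n_lags
  for (v in tv) {
    for (l in seq_len(L)) {
      dt[, (paste0(v, "_lag", l)) := data.table::shift(get(v), l), by = event_id]
    }
  }
  dt <- dt[window_index > L]
  feature_cols <- c(st, tv,
                    unlist(lapply(seq_len(L), function(l) paste0(tv, "_lag", l))))
  keep <- c("event_id", "patient_id", "window_index", "n_windows",
            intersect(c("label_success", "label_bp"), names(dt)),
            feature_cols)
  out <- as.data.frame(dt[, ..keep])
  attr(out, "feature_cols") <- feature_cols
  attr(out, "window_spec") <- spec
  out
}

#' Serialize / load a window table as CSV with a JSON header sidecar
#'
#' @param wt a `gb_window_table`.
#' @param path CSV path; the window spec is written to `<path>.json`.
#' @return `read_window_table` returns the table; `write_window_table`
#'   returns `path` invisibly.
#' @export
write_window_table <- function(wt, path) {
  data.table::fwrite(as.data.frame(wt), path)
  spec <- attr(wt, "window_spec")
  if (!is.null(spec))
    jsonlite::write_json(unclass(spec), paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_window_table
#' @param census census used to restore factor columns.
#' @export
read_window_table <- function(path, census = NULL) {
  wt <- as.data.frame(data.table::fread(path))
  if (!is.null(census)) {
    for (nm in census$name[census$kind == "categorical"]) {
      if (nm %in% names(wt))
        wt[[nm]] <- factor(wt[[nm]], levels = seq_len(census$n_levels[census$name == nm]))
    }
  }
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    sp <- jsonlite::fromJSON(sidecar)
    attr(wt, "window_spec") <- structure(sp, class = "gb_window_spec")
  }
  class(wt) <- c("gb_window_table", "data.frame")
  wt
}
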