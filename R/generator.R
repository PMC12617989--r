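#' Generator configuration
#'
#' Parameters of the synthetic PICU-like cohort generator. Defaults emulate
#' the structure of a realistic PICU cohort: 886 patients, ~1220 intubation events,
#' median intubation duration 4.4 days (IQR 2.2-8.5), a 99-variable census,
#' event-level extubation-success prevalence calibrated to 76.1%, and a
#' continuous blood-pressure-percentile outcome series.
#'
#' Each intubation event carries a latent severity process S_k, an AR(1)
#' series on the 4-hour window grid. Every time-varying variable v follows
#' x_k = loading_v * S_k + e_k with e_k an independent AR(1) series with
#' coefficient rho_v, so variables are both temporally autocorrelated and
#' cross-correlated (which model-based imputers exploit). Binary variables
#' threshold the latent Gaussian; categorical variables bin it. Raw
#' observations are emitted at a per-variable cadence inside each window with
#' small measurement jitter.
#'
#' @param n_patients number of patients.
#' @param reintubation_prob per-patient probability of one additional
#'   intubation event. The default gives E(events) = 886 * (1 + 334/886) = 1220.
#' @param duration_median_days,duration_iqr_days targets for the log-normal
#'   intubation-duration distribution; parameters are solved from the median
#'   and the quartile ratio.
#' @param census a [make_census()] data frame.
#' @param window_hours width of the latent window grid (hours).
#' @param latent_rho AR(1) coefficient of the latent severity process.
#' @param noise_sd marginal SD of each variable's idiosyncratic AR(1) noise.
#' @param jitter_sd SD of measurement jitter added to each raw observation.
#' @param binary_prevalence marginal prevalence at which latent Gaussians are
#'   thresholded for binary variables.
#' @param outcome_coef slope of late-window severity in the logistic model for
#'   extubation success (negative: sicker patients fail). The intercept is
#'   never set directly; it is calibrated by [calibrate_outcome_intercept()]
#'   to `success_prevalence`.
#' @param success_prevalence target event-level prevalence of successful
#'   extubation (default 0.761).
#' @param bp_coef,bp_noise_sd slope of severity and residual SD in the latent
#'   scale of the blood-pressure-percentile outcome
#'   (percentile = 100 * pnorm(bp_coef * S_k + noise)).
#' @param study_period POSIXct length-2 vector over which intubation dates are
#'   drawn uniformly.
#' @param original_missingness `NULL`, or a list with elements `mechanism` and
#'   `proportion` (default proportion 0.182) describing the "original mode"
#'   gaps to punch into the generated window table.
#' @param seed integer seed; fully determines the cohort.
#' @return an object of class `gb_generator_config`.
#' @export
generator_config <- function(n_patients = 886,
                             reintubation_prob = 334 / 886,
                             duration_median_days = 4.4,
                             duration_iqr_days = c(2.2, 8.5),
                             census = default_census(),
                             window_hours = 4,
                             latent_rho = 0.9,
                             noise_sd = 1,
                             jitter_sd = 0.05,
                             binary_prevalence = 0.3,
                             outcome_coef = -1.2,
                             success_prevalence = 0.761,
                             bp_coef = -0.7,
                             bp_noise_sd = 0.5,
                             study_period = as.POSIXct(c("2013-01-01", "2023-03-31"), tz = "UTC"),
                             original_missingness = NULL,
                             seed = 1L) {
  if (n_patients < 1) stop("n_patients must be positive")
  if (any(census$rho < 0 | census$rho >= 1)) stop("AR(1) coefficients must lie in [0, 1)")
  if (reintubation_prob < 0 || reintubation_prob > 1) stop("reintubation_prob must be a probability")
  if (!is.null(original_missingness)) {
    original_missingness$proportion <- original_missingness$proportion %||% 0.182
    original_missingness$mechanism <- original_missingness$mechanism %||% "MAR"
    if (original_missingness$proportion < 0 || original_missingness$proportion >= 1)
      stop("original missingness proportion must lie in [0, 1)")
  }
  cfg <- list(
    n_patients = n_patients, reintubation_prob = reintubation_prob,
    duration_median_days = duration_median_days, duration_iqr_days = duration_iqr_days,
    census = census, window_hours = window_hours, latent_rho = latent_rho,
    noise_sd = noise_sd, jitter_sd = jitter_sd,
    binary_prevalence = binary_prevalence,
    outcome_coef = outcome_coef, success_prevalence = success_prevalence,
    bp_coef = bp_coef, bp_noise_sd = bp_noise_sd,
    study_period = study_period, original_missingness = original_missingness,
    seed = as.integer(seed))
  class(cfg) <- "gb_generator_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## log-normal duration parameters from (median, IQR) targets: meanlog from the
## median, sdlog from the quartile ratio q75/q25 = exp(2 * z75 * sdlog)
duration_lognormal_params <- function(median_days, iqr_days) {
  z75 <- stats::qnorm(0.75)
  list(meanlog = log(median_days * 24),
       sdlog = log(iqr_days[2] / iqr_days[1]) / (2 * z75))
}

## stationary AR(1) series with marginal SD `sd`
ar1_series <- function(n, rho, sd = 1) {
  if (n == 1L) return(stats::rnorm(1, 0, sd))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  innov <- stats::rnorm(n - 1, 0, sd * sqrt(1 - rho^2))
  for (k in 2:n) x[k] <- rho * x[k - 1] + innov[k - 1]
  x
}

#' Calibrate the outcome-model intercept to a target prevalence
#'
#' Solves, by bisection, for the intercept c such that
#' mean(plogis(c + eta)) equals the target prevalence, where `eta` holds the
#' slope part of the linear predictor for each event.
#'
#' @param eta numeric vector of slope-only linear predictor values (use a
#'   vector of zeros for an intercept-only model).
#' @param target_prevalence target probability in (0, 1).
#' @param tol bisection tolerance on the prevalence.
#' @return the intercept (numeric scalar).
#' @export
calibrate_outcome_intercept <- function(eta, target_prevalence, tol = 1e-10) {
  if (target_prevalence <= 0 || target_prevalence >= 1)
    stop("target_prevalence must lie strictly in (0, 1)")
  if (!all(is.finite(eta))) stop("eta must be finite")
  f <- function(c0) mean(stats::plogis(c0 + eta)) - target_prevalence
  lo <- stats::qlogis(target_prevalence) - max(abs(eta), 0) - 1
  hi <- stats::qlogis(target_prevalence) + max(abs(eta), 0) + 1
  if (f(lo) > 0 || f(hi) < 0) stop("target prevalence unattainable for given eta")
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}

## Event table + per-event latent severity (list of numeric vectors on the
## window grid) + outcomes. Shared by generate_cohort() and by cheap
## prevalence studies that do not need raw observations.
simulate_events <- function(config) {
  cfg <- config
  n_extra <- stats::rbinom(cfg$n_patients, 1L, cfg$reintubation_prob)
  patient_id <- rep(seq_len(cfg$n_patients), 1L + n_extra)
  n_events <- length(patient_id)
  event_id <- seq_len(n_events)

  lp <- duration_lognormal_params(cfg$duration_median_days, cfg$duration_iqr_days)
  duration_hours <- stats::rlnorm(n_events, lp$meanlog, lp$sdlog)

  span <- as.numeric(difftime(cfg$study_period[2], cfg$study_period[1], units = "secs"))
  intubation_time <- cfg$study_period[1] + stats::runif(n_events, 0, span)
  ## a patient's repeat intubation occurs after the first
  ord <- order(patient_id, intubation_time)
  intubation_time <- intubation_time[ord]
  extubation_time <- intubation_time + duration_hours * 3600

  n_windows <- pmax(1L, as.integer(ceiling(duration_hours / cfg$window_hours)))
  severity <- lapply(n_windows, ar1_series, rho = cfg$latent_rho, sd = 1)

  ## late-window severity drives the outcome: mean over the final
  ## min(3, K) windows
  sev_late <- vapply(severity, function(s) mean(utils::tail(s, 3L)), numeric(1))
  eta <- cfg$outcome_coef * sev_late
  intercept <- calibrate_outcome_intercept(eta, cfg$success_prevalence)
  success <- stats::rbinom(n_events, 1L, stats::plogis(intercept + eta))

  ## non-success events split into clinically realistic terminal categories
  ## (reintubation, death, tracheostomy, transfer, tube change)
  cat_probs <- c(failure = 100, death = 96, tracheostomy = 36,
                 transfer = 25, ett_change = 34) / 291
  outcome_category <- ifelse(success == 1L, "success",
                             sample(names(cat_probs), n_events, replace = TRUE, prob = cat_probs))

  events <- data.frame(
    patient_id = patient_id, event_id = event_id,
    intubation_time = intubation_time, extubation_time = extubation_time,
    duration_hours = duration_hours, n_windows = n_windows,
    outcome_category = outcome_category,
    success = as.integer(success),
    stringsAsFactors = FALSE)
  list(events = events, severity = severity, intercept = intercept)
}

#' Generate the event table only
#'
#' The event-level fast path: simulates patients, intubation events,
#' durations, latent severity, and calibrated outcomes -- everything except
#' the raw observation stream. Useful for prevalence and duration studies at
#' full cohort scale.
#'
#' @param config a [generator_config()].
#' @return list with `events` (event table incl. `success` and
#'   `outcome_category`) and `intercept` (the calibrated outcome intercept).
#' @export
generate_events <- function(config) {
  stopifnot(inherits(config, "gb_generator_config"))
  set.seed(config$seed)
  sim <- simulate_events(config)
  list(events = sim$events, intercept = sim$intercept)
}

#' Generate a synthetic cohort of raw observations
#'
#' Produces a long-format raw observation table (patient, event, timestamp,
#' variable, value), an event table with outcome labels, and the per-event
#' latent severity used to generate both. Deterministic given `config$seed`.
#'
#' @param config a [generator_config()].
#' @return an object of class `gb_raw_cohort`: list with `observations`
#'   (data.table: patient_id, event_id, timestamp, variable, value),
#'   `events`, `census`, `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "gb_generator_config"))
  set.seed(config$seed)
  sim <- simulate_events(config)
  events <- sim$events
  cen <- config$census
  wh <- config$window_hours

  tv <- cen[!cen$static, , drop = FALSE]
  st <- cen[cen$static & cen$role == "predictor", , drop = FALSE]

  ## static values per patient, constant within and across that patient's events
  n_pat <- max(events$patient_id)
  age <- stats::runif(n_pat, 0.1, 17.9)
  sex <- stats::rbinom(n_pat, 1L, 0.457)
  static_vals <- list(
    age_years = age,
    sex = as.numeric(sex),
    weight_kg = round(exp(1.1 + 0.145 * age + stats::rnorm(n_pat, 0, 0.25)), 1),
    ett_size = round((age / 4 + 4) * 2) / 2)
  for (nm in setdiff(st$name, names(static_vals)))
    static_vals[[nm]] <- stats::rnorm(n_pat)

  obs_list <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    K <- ev$n_windows
    S <- sim$severity[[i]]
    per_var <- vector("list", nrow(tv) + nrow(st))
    j <- 0L
    for (v in seq_len(nrow(tv))) {
      vr <- tv[v, ]
      lat <- vr$loading * S + ar1_series(K, vr$rho, config$noise_sd)
      if (vr$name == "bp_percentile") {
        val_win <- 100 * stats::pnorm(config$bp_coef * S +
                                        stats::rnorm(K, 0, config$bp_noise_sd))
      } else if (vr$kind == "binary") {
        thr <- stats::qnorm(1 - config$binary_prevalence) *
          sqrt(vr$loading^2 + config$noise_sd^2)
        val_win <- as.numeric(lat > thr)
      } else if (vr$kind == "categorical") {
        sdl <- sqrt(vr$loading^2 + config$noise_sd^2)
        br <- stats::qnorm(seq(0, 1, length.out = vr$n_levels + 1L)) * sdl
        val_win <- as.numeric(cut(lat, breaks = br, labels = FALSE,
                                  include.lowest = TRUE))
      } else {
        val_win <- lat
      }
      n_per_win <- max(1L, as.integer(round(wh / vr$cadence_hours)))
      widx <- rep(seq_len(K), each = n_per_win)
      tt <- ev$intubation_time + ((widx - 1) * wh +
        stats::runif(length(widx), 0, wh)) * 3600
      keep <- tt <= ev$extubation_time
      if (!any(keep)) { keep[1] <- TRUE; tt[1] <- ev$intubation_time + 1 }
      vals <- val_win[widx]
      if (vr$kind == "numeric" && vr$name != "bp_percentile")
        vals <- vals + stats::rnorm(length(vals), 0, config$jitter_sd)
      j <- j + 1L
      per_var[[j]] <- data.table::data.table(
        timestamp = tt[keep], variable = vr$name, value = vals[keep])
    }
    for (v in seq_len(nrow(st))) {
      j <- j + 1L
      per_var[[j]] <- data.table::data.table(
        timestamp = ev$intubation_time + 1,
        variable = st$name[v],
        value = static_vals[[st$name[v]]][ev$patient_id])
    }
    ob <- data.table::rbindlist(per_var[seq_len(j)])
    ob[, `:=`(patient_id = ev$patient_id, event_id = ev$event_id)]
    obs_list[[i]] <- ob
  }
  observations <- data.table::rbindlist(obs_list)
  data.table::setcolorder(observations,
                          c("patient_id", "event_id", "timestamp", "variable", "value"))
  data.table::setkey(observations, event_id, variable, timestamp)

  structure(list(observations = observations, events = events,
                 census = cen, config = config,
                 outcome_intercept = sim$intercept),
            class = "gb_raw_cohort")
}

#' @export
print.gb_raw_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients, %d intubation events, %d raw observations\n",
              length(unique(x$events$patient_id)), nrow(x$events),
              nrow(x$observations)))
  cat(sprintf("Extubation success prevalence: %.1f%%\n", 100 * mean(x$events$success)))
  invisible(x)
}

#' Punch "original-mode" gaps into a complete window table
#'
#' Applies the amputation machinery at the configured mechanism and
#' proportion (default 18.2% of cells) to emulate the missingness of the raw
#' study data, returning the gappy table plus flags recording which cells
#' were "originally missing". These flags feed the originally-missing
#' stratification of the evaluation module.
#'
#' @param wt a complete window table (see [collapse_to_windows()]).
#' @param config a [generator_config()] whose `original_missingness` is set;
#'   alternatively a list with `mechanism` and `proportion`.
#' @param census the variable census.
#' @param seed seed for the amputation draw.
#' @return list with `table` (window table with gaps) and `flags` (logical
#'   matrix over the predictor columns, TRUE where a cell was removed).
#' @export
induce_original_missingness <- function(wt, config, census = config$census,
                                        seed = config$seed + 1L) {
  om <- if (inherits(config, "gb_generator_config")) config$original_missingness else config
  om$proportion <- om$proportion %||% 0.182
  om$mechanism <- om$mechanism %||% "MAR"
  if (om$proportion < 0 || om$proportion >= 1)
    stop("original missingness proportion must lie in [0, 1)")
  if (om$proportion == 0) {
    flags <- matrix(FALSE, nrow(wt), length(census_predictors(census)),
                    dimnames = list(NULL, census_predictors(census)))
    return(list(table = wt, flags = flags))
  }
  scen <- missingness_scenario(mechanism = om$mechanism, level = 1,
                               base_cell_proportion = om$proportion,
                               seed = seed)
  amp <- ampute(wt, scen, census)
  list(table = amp$data, flags = amp$mask)
}
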