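# Shared fixtures, memoized so expensive objects are built once per run.

.fx <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

# Small all-numeric census: 10 amputable time-varying variables with AR(1)
# coefficients spread over [0.6, 0.95], one never-missing monitor variable,
# one amputable static (weight).
small_census <- function(ar1_range = c(0.6, 0.95)) {
  make_census(n_numeric_tv = 10, n_binary_tv = 0, n_categorical_tv = 0,
              n_numeric_tv_fixed = 1, n_binary_tv_fixed = 0,
              n_static_amputable = 1, n_static_fixed = 0,
              ar1_range = ar1_range)
}

small_generator <- function(seed = 7, n_patients = 30) {
  generator_config(n_patients = n_patients, reintubation_prob = 0,
                   duration_median_days = 1.5, duration_iqr_days = c(1, 2.5),
                   census = small_census(), seed = seed)
}

# prepared desk cohort (30 events, ~300 window rows, numeric census)
small_prep <- function() memo("small_prep", function() {
  prepare_experiment_data(
    experiment_config("desk", generator = small_generator(), seed = 7))
})

# prepared cohort with the full 99-variable census (>= 50,000 amputable cells)
full_prep <- function() memo("full_prep", function() {
  gen <- generator_config(n_patients = 62, reintubation_prob = 0.2,
                          duration_median_days = 2,
                          duration_iqr_days = c(1.2, 3.4),
                          census = default_census(), seed = 19)
  prepare_experiment_data(experiment_config("desk", generator = gen, seed = 19))
})

outcome_vector <- function(prep) {
  prep$events$success[match(prep$complete$event_id, prep$events$event_id)]
}

# one amputed dataset on the small cohort, shared across imputer tests
small_amputed <- function() memo("small_amputed", function() {
  prep <- small_prep()
  scen <- missingness_scenario("MAR", level = 1, seed = 101)
  ampute(prep$complete, scen, prep$census, outcome = outcome_vector(prep))
})

# a tiny hand-built raw cohort for windowing tests
manual_cohort <- function(obs, intubation, extubation, census,
                          success = 1L) {
  dur <- as.numeric(difftime(extubation, intubation, units = "hours"))
  events <- data.frame(
    patient_id = 1L, event_id = 1L,
    intubation_time = intubation, extubation_time = extubation,
    duration_hours = dur, n_windows = as.integer(ceiling(dur / 4)),
    outcome_category = if (success == 1L) "success" else "failure",
    success = success)
  obs$patient_id <- 1L
  obs$event_id <- 1L
  list(observations = obs, events = events, census = census)
}
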