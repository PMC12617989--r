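tiny_census <- function(categorical = FALSE) {
  make_census(n_numeric_tv = 1, n_binary_tv = 0,
              n_categorical_tv = if (categorical) 1 else 0, n_levels = 4L,
              n_numeric_tv_fixed = 0, n_binary_tv_fixed = 0,
              n_static_amputable = 0, n_static_fixed = 0)
}

test_that("collapsing takes means, modes with latest-wins ties, and leaves gaps", {
  cen <- tiny_census(categorical = TRUE)
  t0 <- as.POSIXct("2018-05-06 17:27:00", tz = "UTC")
  obs <- data.frame(
    timestamp = t0 + c(600, 1200, 3600 * 5, 3600 * 4.2, 3600 * 4.5, 3600 * 4.8),
    variable = c("vital_01", "vital_01", "vital_01", "scale_01", "scale_01", "scale_01"),
    value = c(120, 124, 130, 3, 2, 3))
  cohort <- manual_cohort(obs, t0, t0 + 3600 * 26, cen)
  wt <- collapse_to_windows(cohort)
  expect_equal(wt$vital_01[wt$window_index == 1], 122)   # mean of {120, 124}
  expect_equal(wt$vital_01[wt$window_index == 2], 130)
  expect_true(is.na(wt$vital_01[wt$window_index == 3]))  # no in-window obs

  # mode of {3, 2, 3} is 3; tie case: {2, 3} each once, latest observed wins
  expect_equal(as.character(wt$scale_01[wt$window_index == 2]), "3")
  obs2 <- obs[4:5, ]  # levels 3 then 2, tie -> most recent = 2
  wt2 <- collapse_to_windows(manual_cohort(obs2, t0, t0 + 3600 * 26, cen))
  expect_equal(as.character(wt2$scale_01[wt2$window_index == 2]), "2")
})

test_that("window arithmetic reproduces the worked patient timeline", {
  # patient intubated 17:27 on 5/6/2018: first eligible window (index 3 with
  # two lag windows) must end 12 h later, 05:27 on 5/7/2018
  cen <- tiny_census()
  t0 <- as.POSIXct("2018-05-06 17:27:00", tz = "UTC")
  t_ext <- as.POSIXct("2018-05-08 08:45:00", tz = "UTC")
  obs <- data.frame(timestamp = t0 + 3600 * seq(0.5, 38, by = 1),
                    variable = "vital_01",
                    value = rnorm(38))
  spec <- window_spec()
  wt <- collapse_to_windows(manual_cohort(obs, t0, t_ext, cen), spec)
  expect_equal(spec$first_model_window_end, 12)
  first_eligible <- min(wt$window_index[wt$eligible])
  expect_equal(first_eligible, 3L)
  window_end <- t0 + 3600 * spec$width_hours * first_eligible
  expect_equal(window_end, as.POSIXct("2018-05-07 05:27:00", tz = "UTC"))
  expect_false(any(wt$eligible[wt$window_index <= 2]))
})

test_that("half-open windows partition the period; outside observations are dropped", {
  cen <- tiny_census()
  t0 <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")
  obs <- data.frame(
    timestamp = t0 + 3600 * c(0, 4, 4.0001, 2),  # t0 exactly is outside (left-open)
    variable = "vital_01", value = c(99, 10, 20, 30))
  cohort <- manual_cohort(obs, t0, t0 + 3600 * 25, cen)
  expect_warning(wt <- collapse_to_windows(cohort), "dropped")
  expect_equal(wt$vital_01[wt$window_index == 1], 20)  # mean of {10 (at 4h), 30}
  expect_equal(wt$vital_01[wt$window_index == 2], 20)  # obs just past the boundary
})

test_that("eligibility filtering applies the strict 24-hour rule and age bounds", {
  ev <- data.frame(event_id = 1:3, duration_hours = c(20, 24, 24.5))
  kept <- filter_eligible_events(ev)
  expect_equal(kept$event_id, 3L)
  expect_equal(nrow(filter_eligible_events(ev[0, ])), 0L)

  ev$age_years <- c(5, 5, 19)
  expect_equal(nrow(filter_eligible_events(ev)), 0L)  # survivor now too old
})

test_that("the default census yields 265 lagged features; lag arithmetic is exact", {
  prep <- full_prep()
  wide <- build_lagged_matrix(prep$complete, window_spec(), prep$census)
  expect_length(attr(wide, "feature_cols"), 265L)

  # L = 0 keeps the 99 base variables
  wide0 <- build_lagged_matrix(prep$complete, window_spec(n_lags = 0),
                               prep$census)
  expect_length(attr(wide0, "feature_cols"), 99L)

  # a row at window 3 takes lag1 from window 2 and lag2 from window 1
  wt <- prep$complete
  ev1 <- wt$event_id[1]
  r3 <- wide[wide$event_id == ev1 & wide$window_index == 3, ]
  expect_equal(r3$vital_01_lag1,
               wt$vital_01[wt$event_id == ev1 & wt$window_index == 2])
  expect_equal(r3$vital_01_lag2,
               wt$vital_01[wt$event_id == ev1 & wt$window_index == 1])
  # only eligible rows remain
  expect_true(all(wide$window_index > 2))
  # eligible rows per event = windows - L
  cnt <- table(wide$event_id)
  expect_equal(unname(c(cnt)),
               prep$events$n_windows[match(names(cnt), prep$events$event_id)] - 2L)
})

test_that("labels read terminal status at the lead horizon", {
  cen <- tiny_census()
  t0 <- as.POSIXct("2021-03-01 08:00:00", tz = "UTC")
  obs <- data.frame(timestamp = t0 + 3600 * seq(0.5, 39, 1),
                    variable = "vital_01", value = rnorm(39))
  cohort <- manual_cohort(obs, t0, t0 + 3600 * 40, cen, success = 1L)  # K = 10
  wt <- collapse_to_windows(cohort)
  wt <- assign_labels(wt, cohort$events)
  # success at window K = 10: windows with k + 3 >= 10 are labeled 1
  expect_equal(wt$label_success[wt$window_index == 7], 1L)
  expect_equal(wt$label_success[wt$window_index == 6], 0L)

  cohort_f <- manual_cohort(obs, t0, t0 + 3600 * 40, cen, success = 0L)
  wtf <- assign_labels(collapse_to_windows(cohort_f), cohort_f$events)
  expect_true(all(wtf$label_success == 0L))

  # continuous label is the next window's blood-pressure percentile
  prep <- small_prep()
  wt2 <- prep$complete
  ev1 <- wt2$event_id[1]
  k <- 2
  expect_equal(wt2$label_bp[wt2$event_id == ev1 & wt2$window_index == k],
               wt2$bp_percentile[wt2$event_id == ev1 & wt2$window_index == k + 1])
})
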