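test_that("inverse-frequency weights equalize class mass", {
  y <- c(rep(1, 75), rep(0, 25))
  w <- inverse_frequency_weights(y)
  # minority : majority weight ratio = 3 : 1
  expect_equal(unique(w[y == 0]) / unique(w[y == 1]), 3)
  expect_equal(sum(w[y == 0]), sum(w[y == 1]))
  expect_equal(mean(w), 1)
  expect_error(inverse_frequency_weights(rep(1, 10)), "single class")
})

test_that("cross-validation folds never split an event's windows", {
  set.seed(5)
  groups <- rep(1:40, times = sample(2:8, 40, TRUE))
  foldid <- gapbench:::grouped_foldid(groups, 5)
  per_event <- tapply(foldid, groups, function(f) length(unique(f)))
  expect_true(all(per_event == 1L))
  expect_equal(sort(unique(foldid)), 1:5)
})

test_that("chronological split is date-ordered with patient exclusivity", {
  ev <- data.frame(event_id = 1:4, patient_id = c(1, 2, 3, 4),
                   intubation_time = as.POSIXct("2020-01-01", tz = "UTC") + (1:4) * 86400)
  sp <- chronological_split(ev, 0.75)
  expect_equal(sort(sp$train), 1:3)
  expect_equal(sp$test, 4L)

  # straddling patient follows their earliest event (into training)
  ev2 <- data.frame(event_id = 1:4, patient_id = c(1, 2, 2, 3),
                    intubation_time = as.POSIXct("2020-01-01", tz = "UTC") + c(1, 2, 4, 3) * 86400)
  sp2 <- chronological_split(ev2, 0.75)
  expect_true(all(c(2L, 3L) %in% sp2$train))  # patient 2's later event stays in train
  expect_equal(sp2$test, 4L)

  # at scale: train share within one patient's events of 75%
  set.seed(6)
  pats <- sample(1:300, 400, TRUE)
  ev3 <- data.frame(event_id = 1:400, patient_id = pats,
                    intubation_time = as.POSIXct("2013-01-01", tz = "UTC") +
                      runif(400, 0, 3e8))
  sp3 <- chronological_split(ev3, 0.75)
  expect_false(any(ev3$patient_id[match(sp3$train, ev3$event_id)] %in%
                     ev3$patient_id[match(sp3$test, ev3$event_id)]))
  max_pat <- max(table(pats))
  expect_lt(abs(length(sp3$train) - 300), max_pat + 1)
  expect_error(chronological_split(ev[1, , drop = FALSE]), "at least 2")
})

test_that("gradient boosted models train on incomplete data and emit probabilities", {
  set.seed(11)
  n <- 300
  df <- data.frame(event_id = rep(1:60, each = 5),
                   a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- rbinom(n, 1, plogis(1.5 * df$a - df$b))
  df$a[sample(n, 60)] <- NA  # native missing support
  spec <- outcome_model_spec("gbt", "binary", eta = 0.1, max_depth = 3L,
                             nrounds_max = 50L, seed = 3)
  fit <- fit_outcome_model(spec, df, y, feature_cols = c("a", "b", "c"))
  p <- predict(fit, df)
  expect_true(all(p >= 0 & p <= 1))
  # signal learned: better than chance on training data
  expect_gt(mean((p > 0.5) == y), 0.6)
  # deterministic given seed
  fit2 <- fit_outcome_model(spec, df, y, feature_cols = c("a", "b", "c"))
  expect_equal(predict(fit2, df), p)
  expect_error(fit_outcome_model(spec, df, rep(1, n)), "single class")
})

test_that("the L1 model requires complete data and handles continuous outcomes", {
  set.seed(12)
  n <- 250
  df <- data.frame(event_id = rep(1:50, each = 5),
                   a = rnorm(n), b = rnorm(n))
  y <- 2 * df$a + rnorm(n, sd = 0.3)
  spec <- outcome_model_spec("l1", "continuous", seed = 2)
  fit <- fit_outcome_model(spec, df, y, feature_cols = c("a", "b"))
  pred <- predict(fit, df)
  expect_gt(cor(pred, y), 0.9)

  df_na <- df; df_na$a[5] <- NA
  expect_error(fit_outcome_model(spec, df_na, y, feature_cols = c("a", "b")),
               "cannot accommodate missing")
  expect_error(predict(fit, df_na), "cannot accommodate missing")
})

test_that("multiple-imputation ensembling averages member predictions exactly", {
  set.seed(13)
  n <- 200
  mk <- function(seed) {
    df <- data.frame(event_id = rep(1:40, each = 5), a = rnorm(n), b = rnorm(n))
    df
  }
  d1 <- mk(1); d2 <- mk(2)
  y <- rbinom(n, 1, plogis(d1$a))
  spec <- outcome_model_spec("gbt", "binary", eta = 0.1, max_depth = 3L,
                             nrounds_max = 30L, seed = 7)
  m1 <- fit_outcome_model(spec, d1, y, feature_cols = c("a", "b"))
  m2 <- fit_outcome_model(spec, d2, y, feature_cols = c("a", "b"))
  te1 <- mk(3); te2 <- mk(4)
  ens <- mi_ensemble_predict(list(m1, m2), list(te1, te2))
  expect_equal(ens, (predict(m1, te1) + predict(m2, te2)) / 2)
  # identical members reproduce the member
  expect_equal(mi_ensemble_predict(list(m1, m1), list(te1, te1)), predict(m1, te1))
  expect_error(mi_ensemble_predict(list(m1, m2), list(te1)), "differ")
})
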