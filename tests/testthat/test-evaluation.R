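fake_ctx <- function(n = 50, seed = 1) {
  set.seed(seed)
  complete <- data.frame(u = rnorm(n, 10, 2), w = rnorm(n, 0, 5),
                         f = factor(sample(c("A", "B"), n, TRUE, prob = c(0.7, 0.3))))
  mask <- cbind(u = rep(c(TRUE, FALSE), length.out = n),
                w = rep(c(FALSE, TRUE), length.out = n),
                f = rep(c(TRUE, FALSE), length.out = n))
  eval_context(complete, mask)
}

test_that("standardized MSE is zero for perfect imputation and ignores observed cells", {
  ctx <- fake_ctx()
  expect_equal(imputation_mse(ctx, ctx$complete)$overall, 0)
  # corrupting only unmasked cells changes nothing
  imp <- ctx$complete
  imp$u[!ctx$mask[, "u"]] <- 999
  expect_equal(imputation_mse(ctx, imp)$overall, 0)
  # a known displacement in SD units
  imp2 <- ctx$complete
  imp2$u[ctx$mask[, "u"]] <- imp2$u[ctx$mask[, "u"]] + ctx$sds[["u"]]
  expect_equal(imputation_mse(ctx, imp2)$per_variable[["u"]], 1)
})

test_that("classification error spans its range and matches the mode-imputation oracle", {
  ctx <- fake_ctx()
  expect_equal(classification_error(ctx, ctx$complete)$overall, 0)
  imp <- ctx$complete
  masked <- ctx$mask[, "f"]
  imp$f[masked] <- factor(ifelse(ctx$complete$f[masked] == "A", "B", "A"),
                          levels = levels(ctx$complete$f))
  expect_equal(classification_error(ctx, imp)$overall, 1)

  # mode imputation of a 0.7-prevalent binary factor under MCAR errs ~0.3
  set.seed(14)
  n <- 4000
  complete <- data.frame(f = factor(sample(c("A", "B"), n, TRUE, c(0.7, 0.3))))
  mask <- cbind(f = runif(n) < 0.5)
  ctx2 <- eval_context(complete, mask)
  imp2 <- complete
  imp2$f[mask[, "f"]] <- "A"
  expect_lt(abs(classification_error(ctx2, imp2)$overall - 0.3), 0.03)
})

test_that("classification metrics satisfy their defining identities", {
  # constructed confusion: sens 0.8, spec 0.6
  labels <- c(rep(1, 10), rep(0, 10))
  scores <- c(rep(0.9, 8), rep(0.1, 2), rep(0.9, 4), rep(0.1, 6))
  m <- prediction_metrics(labels, scores, "binary")
  expect_equal(m[["sensitivity"]], 0.8)
  expect_equal(m[["specificity"]], 0.6)
  expect_equal(m[["balanced_accuracy"]], 0.7)
  expect_equal(m[["balanced_accuracy"]],
               (m[["sensitivity"]] + m[["specificity"]]) / 2)
  expect_equal(m[["f1"]],
               2 * m[["ppv"]] * m[["sensitivity"]] / (m[["ppv"]] + m[["sensitivity"]]))

  # perfect classifier
  mp <- prediction_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9), "binary")
  expect_equal(mp[["balanced_accuracy"]], 1)
  expect_equal(mp[["auc"]], 1)

  # single-class labels: AUC absent
  ms <- prediction_metrics(c(1, 1, 1), c(0.2, 0.6, 0.9), "binary")
  expect_true(is.na(ms[["auc"]]))

  # continuous identities
  set.seed(15)
  y <- rnorm(100); s <- y + rnorm(100, sd = 0.5)
  mc <- prediction_metrics(y, s, "continuous")
  expect_equal(mc[["rmse"]]^2, mc[["mse"]])
  expect_equal(mc[["mse"]], mean((s - y)^2))
})

test_that("AUC is invariant under monotone score transforms and ~0.5 for noise", {
  set.seed(16)
  y <- rbinom(2000, 1, 0.5)
  s <- runif(2000)
  a1 <- prediction_metrics(y, s, "binary")[["auc"]]
  a2 <- prediction_metrics(y, qlogis(s * 0.98 + 0.01), "binary")[["auc"]]
  expect_equal(a1, a2)
  expect_lt(abs(a1 - 0.5), 0.05)
})

test_that("variability and overfit summaries follow their formulas", {
  rp <- data.frame(
    mechanism = "MCAR", level = 1, replicate = 1,
    method = rep(c("mean", "locf"), each = 2),
    partition = rep(c("train", "test"), 2),
    metric = "balanced_accuracy",
    value = c(1, 1, 3, 3))
  vo <- variability_and_overfit(rp, "balanced_accuracy")
  expect_equal(vo$cv, sd(c(1, 3)) / mean(c(1, 3)))  # 0.7071
  expect_equal(vo$cv, 0.7071, tolerance = 1e-4)
  expect_true(all(vo$overfit$gap == 0))

  rp$value <- c(2, 2, 2, 2)
  expect_equal(variability_and_overfit(rp, "balanced_accuracy")$cv, 0)
})

test_that("pooled AR(1) estimates recover white noise and persistent series", {
  set.seed(17)
  wt <- data.frame(event_id = rep(1:30, each = 20), window_index = rep(1:20, 30))
  wt$noise <- rnorm(600)
  x <- numeric(600)
  for (ev in split(seq_len(600), wt$event_id)) {
    z <- numeric(length(ev)); z[1] <- rnorm(1)
    for (k in 2:length(ev)) z[k] <- 0.9 * z[k - 1] + rnorm(1, 0, sqrt(1 - 0.81))
    x[ev] <- z
  }
  wt$persistent <- x
  ar1 <- ar1_by_variable(wt, c("noise", "persistent"))
  expect_lt(abs(ar1[["noise"]]), 0.1)
  expect_lt(abs(ar1[["persistent"]] - 0.9), 0.07)
  wt$const <- 1
  expect_true(is.na(ar1_by_variable(wt, "const")[["const"]]))
})

test_that("originally-missing strata partition the evaluated cells and recombine", {
  ctx0 <- fake_ctx(n = 200, seed = 18)
  set.seed(19)
  flags <- ctx0$mask & cbind(u = runif(200) < 0.5,
                             w = runif(200) < 0.5, f = rep(FALSE, 200))
  ctx <- eval_context(ctx0$complete, ctx0$mask, original_flags = flags)
  imp <- ctx$complete
  imp$u[ctx$mask[, "u"]] <- imp$u[ctx$mask[, "u"]] + 1
  imp$w[ctx$mask[, "w"]] <- imp$w[ctx$mask[, "w"]] + 1
  strat <- stratify_by_original_missingness(ctx, imp)
  expect_setequal(strat$stratum, c("originally_missing", "originally_observed"))

  # per-variable identity: cell-count weighted mean of stratum MSEs = pooled
  pooled <- imputation_mse(ctx, imp)$per_variable[["u"]]
  m1 <- imputation_mse(ctx, imp, cells = ctx$mask & flags)$per_variable[["u"]]
  m2 <- imputation_mse(ctx, imp, cells = ctx$mask & !flags)$per_variable[["u"]]
  n1 <- sum(ctx$mask[, "u"] & flags[, "u"]); n2 <- sum(ctx$mask[, "u"] & !flags[, "u"])
  expect_equal((n1 * m1 + n2 * m2) / (n1 + n2), pooled)

  # absent flags: single stratum with a notice
  expect_message(s0 <- stratify_by_original_missingness(ctx0, imp), "absent")
  expect_equal(s0$stratum, "all")
})
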