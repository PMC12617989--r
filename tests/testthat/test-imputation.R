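toy_train <- function() {
  data.frame(event_id = rep(1:3, each = 2), window_index = rep(1:2, 3),
             x = c(2, 4, 2, 4, 2, 4),
             y = c(10, NA, 12, 14, NA, 18),
             f = factor(c("A", "A", "B", NA, "A", "B"), levels = c("A", "B", "C")))
}

test_that("mean imputation stores and applies training means and modes", {
  fit <- fit_imputer(imputer_spec("mean"), toy_train())
  expect_equal(fit$means$x, 3)
  expect_equal(fit$modes$f, "A")
  new <- data.frame(event_id = 9L, window_index = 1L, x = NA_real_,
                    y = NA_real_, f = factor(NA, levels = c("A", "B", "C")))
  out <- apply_imputer(fit, new)$average
  expect_equal(out$x, 3)
  expect_equal(as.character(out$f), "A")
  # deterministic methods produce a single imputation regardless of m
  expect_equal(apply_imputer(fit, new, m = 10)$m, 1L)
})

test_that("the none method is a pure passthrough and complete input is an identity", {
  tr <- toy_train()
  fit <- fit_imputer(imputer_spec("none"), tr)
  out <- apply_imputer(fit, tr)
  expect_identical(out$average, tr)
  # every method is an identity on complete rows
  complete_rows <- tr[!is.na(tr$y) & !is.na(tr$f), ]
  for (meth in c("mean", "locf", "none")) {
    f2 <- fit_imputer(imputer_spec(meth), tr)
    expect_identical(apply_imputer(f2, complete_rows)$average[, c("x", "y", "f")],
                     complete_rows[, c("x", "y", "f")],
                     label = meth)
  }
})

test_that("LOCF carries forward indefinitely, never backward, never future", {
  expect_equal(locf_impute(c(5, NA, NA)), c(5, 5, 5))
  expect_equal(locf_impute(c(NA, 7)), c(NA, 7))
  expect_equal(locf_impute(c(3, 1, 2)), c(3, 1, 2))
  expect_equal(locf_impute(c(NA, 4, NA, 9, NA)), c(NA, 4, 4, 9, 9))
  f <- factor(c("b", NA, "a", NA), levels = c("a", "b"))
  expect_equal(as.character(locf_impute(f)), c("b", "b", "a", "a"))

  # through the fitted-imputer surface, per event, with window ordering
  tr <- data.frame(event_id = c(1, 1, 1, 2, 2), window_index = c(1, 2, 3, 1, 2),
                   v = c(5, NA, NA, NA, 7))
  fit <- fit_imputer(imputer_spec("locf"), tr)
  out <- apply_imputer(fit, tr)$average
  expect_equal(out$v, c(5, 5, 5, NA, 7))
  # mean fallback flag resolves leading gaps from training means
  fit2 <- fit_imputer(imputer_spec("locf", locf_fallback = "mean"), tr)
  out2 <- apply_imputer(fit2, tr)$average
  expect_equal(out2$v[4], mean(c(5, 7)))
})

test_that("outcome columns are refused unless explicitly excluded", {
  tr <- toy_train()
  tr$label_success <- c(1, 0, 1, 0, 1, 0)
  expect_error(fit_imputer(imputer_spec("mean"), tr), "outcome")
  fit <- fit_imputer(imputer_spec("mean"), tr, exclude = "label_success")
  # imputations invariant to any permutation of the excluded outcome
  tr2 <- tr; tr2$label_success <- rev(tr2$label_success)
  fit2 <- fit_imputer(imputer_spec("mean"), tr2, exclude = "label_success")
  expect_identical(fit, fit2)
})

test_that("donor methods return observed training values; PMM stays in range", {
  prep <- small_prep()
  amp <- small_amputed()
  wide <- build_lagged_matrix(amp$data, window_spec(), prep$census)
  tr <- wide$event_id %in% prep$split$train
  train <- wide[tr, ]; test <- wide[!tr, ]
  lab <- grep("^label_", names(wide), value = TRUE)
  args <- list(n_trees = 30L, chained_iters = 2L, seed = 5)

  for (meth in c("rf_donor", "bayes_pmm")) {
    spec <- do.call(imputer_spec, c(list(method = meth, m = 3L), args))
    fit <- fit_imputer(spec, train, census = prep$census, exclude = lab)
    bundle <- apply_imputer(fit, test[, setdiff(names(test), lab)], m = 3L)
    n_draws <- 0
    for (v in c("vital_01", "vital_05", "vital_10")) {
      obs_vals <- train[[v]][!is.na(train[[v]])]
      for (im in bundle$imputations) {
        filled <- im[[v]][is.na(test[[v]])]
        n_draws <- n_draws + length(filled)
        expect_true(all(filled %in% obs_vals),
                    label = sprintf("%s donor membership for %s", meth, v))
      }
      # range containment follows from donor membership
      expect_true(all(bundle$average[[v]] >= min(obs_vals) - 1e-9 |
                        !is.na(test[[v]])))
    }
    expect_gt(n_draws, 50)
  }
})

test_that("PMM with one donor and noiseless linear data returns the nearest donor", {
  set.seed(8)
  n <- 60
  x <- rnorm(n)
  y <- 2 * x + 1          # exact linear relation, zero noise
  y[c(3, 17, 41)] <- NA
  tr <- data.frame(x = x, y = y)
  spec <- imputer_spec("bayes_pmm", m = 1L, k_donors = 1L, chained_iters = 1L,
                       seed = 4)
  fit <- fit_imputer(spec, tr)
  out <- apply_imputer(fit, tr, m = 1L)$average
  for (i in c(3, 17, 41)) {
    donors <- which(!is.na(y))
    nearest <- donors[which.min(abs(x[donors] - x[i]))]
    expect_equal(out$y[i], 2 * x[nearest] + 1)
  }
})

test_that("bootstrap-LASSO imputes plausibly for numeric and categorical kinds", {
  prep <- small_prep()
  amp <- small_amputed()
  wt <- amp$data
  # add an amputable-style categorical column with gaps for the tree path
  set.seed(9)
  wt$scale_x <- factor(sample(c("1", "2", "3"), nrow(wt), TRUE),
                       levels = c("1", "2", "3"))
  wt$scale_x[sample(nrow(wt), 40)] <- NA
  spec <- imputer_spec("lasso_boot", m = 3L, chained_iters = 1L, seed = 6)
  cols <- c("event_id", "window_index", "vital_01", "vital_02", "vital_03",
            "weight_kg", "scale_x")
  fit <- fit_imputer(spec, wt[, cols])
  out <- apply_imputer(fit, wt[, cols], m = 3L)
  for (im in out$imputations) {
    expect_false(anyNA(im$vital_01))
    expect_true(all(is.finite(im$vital_01)))
    expect_true(all(as.character(im$scale_x) %in% c("1", "2", "3")))
  }
  # infinite penalty collapses the linear predictor to the intercept
  set.seed(10)
  X <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  yy <- rnorm(100, 5)
  b <- gapbench:::lasso_boot_one(X, yy, lambda = 1e9, mean_y = mean(yy))
  expect_lt(abs(b$a0 - mean(yy)), 0.5)
  expect_true(is.null(b$beta) || all(abs(b$beta) < 1e-8))
})

test_that("averaging imputations is exact and can only improve squared error", {
  prep <- small_prep()
  tr <- toy_train()
  fit <- fit_imputer(imputer_spec("mean"), tr)
  b <- apply_imputer(fit, tr)
  expect_identical(average_imputations(b), b$imputations[[1]])

  # numeric average and categorical per-cell mode
  imps <- list(data.frame(v = c(1, 5), f = factor(c("A", "B"), levels = c("A", "B", "C"))),
               data.frame(v = c(3, 5), f = factor(c("A", "C"), levels = c("A", "B", "C"))),
               data.frame(v = c(2, 5), f = factor(c("B", "C"), levels = c("A", "B", "C"))))
  fake_fit <- list(cols = c("v", "f"), kinds = c(v = "numeric", f = "categorical"),
                   levels = list(v = NULL, f = c("A", "B", "C")))
  avg <- gapbench:::average_imputations_list(imps, fake_fit)
  expect_equal(avg$v, c(2, 5))
  expect_equal(as.character(avg$f), c("A", "C"))

  # per-cell Jensen inequality: (mean(y_j) - t)^2 <= mean((y_j - t)^2)
  amp <- small_amputed()
  wide <- build_lagged_matrix(amp$data, window_spec(), prep$census)
  trn <- wide[wide$event_id %in% prep$split$train, ]
  lab <- grep("^label_", names(wide), value = TRUE)
  spec <- imputer_spec("rf_donor", m = 5L, n_trees = 30L, chained_iters = 1L, seed = 2)
  f <- fit_imputer(spec, trn, census = prep$census, exclude = lab)
  bu <- apply_imputer(f, trn[, setdiff(names(trn), lab)], m = 5L)
  wide_c <- build_lagged_matrix(prep$complete, window_spec(), prep$census)
  truth <- wide_c[wide_c$event_id %in% prep$split$train, ]
  v <- "vital_04"
  idx <- is.na(trn[[v]])
  t_true <- truth[[v]][idx]
  err_avg <- mean((bu$average[[v]][idx] - t_true)^2)
  err_mem <- mean(sapply(bu$imputations, function(d) mean((d[[v]][idx] - t_true)^2)))
  expect_lte(err_avg, err_mem + 1e-12)
})

test_that("fitting is a pure function of the training data and seed", {
  prep <- small_prep()
  amp <- small_amputed()
  wide <- build_lagged_matrix(amp$data, window_spec(), prep$census)
  trn <- wide[wide$event_id %in% prep$split$train, ]
  lab <- grep("^label_", names(wide), value = TRUE)
  spec <- imputer_spec("bayes_pmm", m = 2L, chained_iters = 1L, seed = 31)
  f1 <- fit_imputer(spec, trn, census = prep$census, exclude = lab)
  f2 <- fit_imputer(spec, trn, census = prep$census, exclude = lab)
  expect_identical(f1, f2)
  # applying with a fixed seed is reproducible
  tst <- wide[!(wide$event_id %in% prep$split$train), setdiff(names(wide), lab)]
  a1 <- apply_imputer(f1, tst, m = 2L, seed = 99)
  a2 <- apply_imputer(f2, tst, m = 2L, seed = 99)
  expect_identical(a1$imputations, a2$imputations)
})

test_that("mean imputation shrinks per-variable variance", {
  prep <- small_prep()
  amp <- small_amputed()
  cols <- c("event_id", "window_index",
            prep$census$name[prep$census$role == "predictor"])
  fit <- fit_imputer(imputer_spec("mean"), amp$data[, cols])
  out <- apply_imputer(fit, amp$data[, cols])
  v <- "vital_06"
  expect_lt(var(out$average[[v]]), var(prep$complete[[v]]))
})
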