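#' Imputer specification
#'
#' Controls for the six missing-data strategies. All strategies obey the same
#' contract: state is learned from training rows only (never the outcome),
#' and applying to new rows -- including a single row -- requires no
#' refitting.
#'
#' Methods:
#' \itemize{
#'   \item `mean`: unconditional training mean (numeric/binary) or mode
#'     (categorical).
#'   \item `locf`: last observation carried forward indefinitely within an
#'     event; cells with no prior observation remain missing (or fall back to
#'     the training mean when `locf_fallback = "mean"`).
#'   \item `rf_donor`: per-variable random forests; donors are training
#'     observations sharing a terminal node with the target, one donor's
#'     observed value sampled uniformly.
#'   \item `bayes_pmm`: Bayesian normal linear model with predictive mean
#'     matching among the `k_donors` prediction-nearest training donors.
#'   \item `lasso_boot`: L1-penalized regressions on bootstrap samples of the
#'     observed training data; imputations drawn from the fitted predictive
#'     distributions. Multi-level categorical variables use a classification
#'     tree (leaf class frequencies sampled).
#'   \item `none`: passthrough for outcome models with native missing-value
#'     support.
#' }
#'
#' Model-based methods (`rf_donor`, `bayes_pmm`, `lasso_boot`) are trained by
#' chained equations on the training matrix: missing cells initialized at
#' training means/modes, variables visited in order of increasing
#' missingness, `chained_iters` sweeps, final per-variable models and donor
#' pools stored.
#'
#' @param method one of the six strategies above.
#' @param m number of imputations (default 30; deterministic methods ignore
#'   it and produce one).
#' @param k_donors donor-pool size for predictive mean matching.
#' @param n_trees,max_depth random-forest controls.
#' @param chained_iters chained-equation sweeps (fit and apply).
#' @param locf_fallback `"none"` (cells with no prior value stay missing) or
#'   `"mean"` (training-mean fallback, for complete-data outcome models).
#' @param seed integer seed used by [fit_imputer()].
#' @return an object of class `gb_imputer_spec`.
#' @export
imputer_spec <- function(method = c("mean", "locf", "rf_donor", "bayes_pmm",
                                    "lasso_boot", "none"),
                         m = 30L, k_donors = 5L, n_trees = 100L,
                         max_depth = NULL, chained_iters = 5L,
                         locf_fallback = c("none", "mean"), seed = 1L) {
  method <- match.arg(method)
  locf_fallback <- match.arg(locf_fallback)
  stopifnot(m >= 1, k_donors >= 1, chained_iters >= 1)
  structure(list(method = method, m = as.integer(m),
                 k_donors = as.integer(k_donors),
                 n_trees = as.integer(n_trees), max_depth = max_depth,
                 chained_iters = as.integer(chained_iters),
                 locf_fallback = locf_fallback, seed = as.integer(seed)),
            class = "gb_imputer_spec")
}

is_deterministic_method <- function(method) method %in% c("mean", "locf", "none")

ID_COLS <- c("event_id", "patient_id", "window_index", "n_windows", "eligible")

modeling_columns <- function(df) {
  setdiff(names(df), c(ID_COLS, grep("^label_", names(df), value = TRUE)))
}

## dummy-expand a data frame into a numeric design matrix; factor columns
## become level indicators (first level dropped)
build_design <- function(df, cols, kinds, levels) {
  mats <- lapply(cols, function(v) {
    x <- df[[v]]
    if (kinds[[v]] == "categorical") {
      lev <- levels[[v]]
      m <- 1 * outer(as.character(x), lev[-1], "==")
      colnames(m) <- paste0(v, "..", lev[-1])
      m
    } else matrix(as.numeric(x), ncol = 1, dimnames = list(NULL, v))
  })
  do.call(cbind, mats)
}

design_colnames <- function(v, kinds, levels) {
  if (kinds[[v]] == "categorical") paste0(v, "..", levels[[v]][-1]) else v
}

#' Fit an imputer on training rows
#'
#' Learns the method's state from the training matrix only. The outcome must
#' not be present: columns whose names begin with `label_` are refused unless
#' listed in `exclude` (in which case they are dropped before fitting), so an
#' imputation model can never leak outcome information.
#'
#' @param spec an [imputer_spec()].
#' @param train training rows: id columns (`event_id`, `window_index`, ...)
#'   plus feature columns (numeric, or factor for categorical).
#' @param census optional census, accepted for interface symmetry with the
#'   pipeline stages; column kinds are inferred from the columns themselves
#'   (factor = categorical, everything else numeric, so binary window means
#'   are handled as numeric throughout, mirroring how they are evaluated).
#' @param exclude columns to drop before fitting (e.g. outcome labels).
#' @return an object of class `gb_fitted_imputer`.
#' @export
fit_imputer <- function(spec, train, census = NULL, exclude = character()) {
  stopifnot(inherits(spec, "gb_imputer_spec"))
  train <- train[, setdiff(names(train), exclude), drop = FALSE]
  labs <- grep("^label_", names(train), value = TRUE)
  if (length(labs) > 0)
    stop("outcome columns present in imputer training data: ",
         paste(labs, collapse = ", "), " (drop them or list them in `exclude`)")
  cols <- modeling_columns(train)
  if (length(cols) == 0L) stop("no feature columns to fit on")

  kinds <- vapply(cols, function(v) {
    if (is.factor(train[[v]])) "categorical" else "numeric"
  }, character(1))
  levels <- lapply(cols, function(v)
    if (is.factor(train[[v]])) levels(train[[v]]) else NULL)
  names(levels) <- cols

  means <- modes <- stats::setNames(vector("list", length(cols)), cols)
  for (v in cols) {
    x <- train[[v]]
    if (kinds[[v]] == "categorical") {
      tab <- table(x)
      if (sum(tab) == 0L) {
        message(sprintf("variable '%s' has no observed training values; using first level", v))
        modes[[v]] <- levels[[v]][1]
      } else modes[[v]] <- names(tab)[which.max(tab)]
    } else {
      mu <- mean(x, na.rm = TRUE)
      if (!is.finite(mu)) {
        message(sprintf("variable '%s' has no observed training values; using 0", v))
        mu <- 0
      }
      means[[v]] <- mu
    }
  }

  fit <- list(method = spec$method, spec = spec, cols = cols, kinds = kinds,
              levels = levels, means = means, modes = modes,
              n_train = nrow(train), version = 1L)
  class(fit) <- "gb_fitted_imputer"
  if (spec$method %in% c("mean", "locf", "none")) return(fit)

  set.seed(spec$seed)
  miss_n <- vapply(cols, function(v) sum(is.na(train[[v]])), integer(1))
  visit <- cols[miss_n > 0][order(miss_n[miss_n > 0])]
  fit$visit <- visit
  obs_idx <- lapply(cols, function(v) which(!is.na(train[[v]])))
  names(obs_idx) <- cols

  filled <- init_fill(train, fit)
  models <- stats::setNames(vector("list", length(visit)), visit)
  lambda <- stats::setNames(rep(NA_real_, length(visit)), visit)

  for (it in seq_len(spec$chained_iters)) {
    for (v in visit) {
      oi <- obs_idx[[v]]
      if (length(oi) < 3L) { models[[v]] <- list(type = "fallback"); next }
      mi <- setdiff(seq_len(nrow(train)), oi)
      mod <- fit_var_model(spec, v, filled, oi, fit, lambda_cached = lambda[[v]])
      if (!is.null(mod$lambda)) lambda[[v]] <- mod$lambda
      models[[v]] <- mod
      if (length(mi) > 0) {
        filled[[v]][mi] <- draw_var(spec, mod, v, filled, mi, fit)
      }
    }
  }
  ## lasso_boot: one bootstrap model set per imputation, fitted on the final
  ## chained-equation state
  if (spec$method == "lasso_boot") {
    for (v in visit) {
      if (identical(models[[v]]$type, "fallback")) next
      if (fit$kinds[[v]] == "categorical") next
      models[[v]] <- lasso_boot_finalize(spec, v, filled, obs_idx[[v]], fit,
                                         lambda[[v]], models[[v]])
    }
  }
  fit$models <- models
  fit
}

init_fill <- function(rows, fit) {
  for (v in fit$cols) {
    idx <- is.na(rows[[v]])
    if (!any(idx)) next
    if (fit$kinds[[v]] == "categorical") {
      rows[[v]][idx] <- fit$modes[[v]]
    } else rows[[v]][idx] <- fit$means[[v]]
  }
  rows
}

## fit the per-variable model for one chained-equation visit
fit_var_model <- function(spec, v, filled, oi, fit, lambda_cached = NA_real_) {
  others <- setdiff(fit$cols, v)
  y <- filled[[v]][oi]
  if (fit$kinds[[v]] != "categorical" && stats::sd(y) == 0)
    return(list(type = "fallback"))

  if (spec$method == "rf_donor") {
    xdf <- filled[oi, others, drop = FALSE]
    forest <- ranger::ranger(
      x = xdf, y = y, num.trees = spec$n_trees,
      max.depth = spec$max_depth %||% 0,
      num.threads = 1L, seed = sample.int(.Machine$integer.max, 1),
      verbose = FALSE)
    tn_obs <- stats::predict(forest, data = xdf, type = "terminalNodes",
                             num.threads = 1L)$predictions
    return(list(type = "rf", forest = forest, tn_obs = tn_obs, y_obs = y,
                others = others))
  }

  if (fit$kinds[[v]] == "categorical") {
    ## multi-level categorical response: classification tree (the L1 and
    ## normal-linear machinery does not accommodate multiclass responses)
    dat <- filled[oi, others, drop = FALSE]
    dat$.y <- factor(y, levels = fit$levels[[v]])
    tree <- rpart::rpart(.y ~ ., data = dat, method = "class",
                         control = rpart::rpart.control(cp = 0.01, minbucket = 5))
    return(list(type = "tree", tree = tree, others = others,
                levels = fit$levels[[v]]))
  }

  X <- build_design(filled, others, fit$kinds, fit$levels)
  Xo <- X[oi, , drop = FALSE]

  if (spec$method == "bayes_pmm") {
    return(c(bayes_norm_fit(Xo, y), list(type = "bayes", others = others)))
  }

  ## lasso_boot sweep model: one bootstrap L1 fit at the CV-chosen penalty
  if (is.na(lambda_cached)) {
    lambda_cached <- tryCatch(
      glmnet::cv.glmnet(Xo, y, nfolds = 5)$lambda.min,
      error = function(e) NA_real_)
  }
  bm <- lasso_boot_one(Xo, y, lambda_cached, mean_y = mean(y))
  list(type = "lasso", boots = list(bm), lambda = lambda_cached,
       others = others)
}

## Bayesian normal linear model sufficient statistics (small ridge for
## stability; predictors standardized with stored center/scale)
bayes_norm_fit <- function(X, y, ridge = 1e-5) {
  center <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  Xs <- cbind(`(Intercept)` = 1, sweep(sweep(X, 2, center), 2, scl, "/"))
  p <- ncol(Xs)
  A <- crossprod(Xs) + diag(ridge, p)
  beta <- solve(A, crossprod(Xs, y))
  yhat <- drop(Xs %*% beta)
  rss <- sum((y - yhat)^2)
  df <- max(length(y) - p, 1L)
  V <- solve(A)
  list(center = center, scale = scl, beta = drop(beta),
       cholV = chol((V + t(V)) / 2), rss = rss, df = df,
       yhat_obs = yhat, y_obs = y)
}

bayes_design <- function(model, Xnew) {
  cbind(1, sweep(sweep(Xnew, 2, model$center), 2, model$scale, "/"))
}

## one bootstrap L1 fit; returns coefficients + residual scale
lasso_boot_one <- function(X, y, lambda, mean_y) {
  n <- length(y)
  idx <- sample.int(n, n, replace = TRUE)
  yb <- y[idx]
  if (stats::sd(yb) == 0 || !is.finite(lambda)) {
    return(list(a0 = mean(yb), beta = NULL, sigma = stats::sd(y)))
  }
  g <- glmnet::glmnet(X[idx, , drop = FALSE], yb, lambda = lambda)
  pred <- drop(stats::predict(g, X[idx, , drop = FALSE]))
  list(a0 = g$a0[1], beta = as.matrix(g$beta)[, 1],
       sigma = max(stats::sd(yb - pred), 1e-8))
}

lasso_boot_finalize <- function(spec, v, filled, oi, fit, lambda, model) {
  others <- setdiff(fit$cols, v)
  X <- build_design(filled, others, fit$kinds, fit$levels)[oi, , drop = FALSE]
  y <- filled[[v]][oi]
  boots <- lapply(seq_len(spec$m), function(j)
    lasso_boot_one(X, y, lambda, mean_y = mean(y)))
  list(type = "lasso", boots = boots, lambda = lambda, others = others)
}

## stochastic draw of imputed values for rows `mi` of variable v
## `imp_index` selects the bootstrap coefficient set for lasso_boot
draw_var <- function(spec, model, v, filled, mi, fit, imp_index = 1L) {
  n_mi <- length(mi)
  if (identical(model$type, "fallback") || is.null(model)) {
    return(if (fit$kinds[[v]] == "categorical")
      rep(fit$modes[[v]], n_mi) else rep(fit$means[[v]], n_mi))
  }
  if (model$type == "rf") {
    tn_new <- stats::predict(model$forest, data = filled[mi, model$others, drop = FALSE],
                             type = "terminalNodes", num.threads = 1L)$predictions
    trees <- sample.int(ncol(tn_new), n_mi, replace = TRUE)
    out <- vector(mode = if (is.factor(model$y_obs)) "character" else "numeric", n_mi)
    for (i in seq_len(n_mi)) {
      t <- trees[i]
      donors <- which(model$tn_obs[, t] == tn_new[i, t])
      if (length(donors) == 0L) {
        out[i] <- if (is.factor(model$y_obs)) fit$modes[[v]] else fit$means[[v]]
      } else {
        pick <- donors[sample.int(length(donors), 1L)]
        out[i] <- if (is.factor(model$y_obs)) as.character(model$y_obs[pick]) else model$y_obs[pick]
      }
    }
    return(out)
  }
  if (model$type == "tree") {
    pr <- stats::predict(model$tree, newdata = filled[mi, model$others, drop = FALSE],
                         type = "prob")
    lev <- colnames(pr)
    vapply(seq_len(n_mi), function(i)
      sample(lev, 1L, prob = pr[i, ]), character(1))
  } else if (model$type == "bayes") {
    X <- build_design(filled, model$others, fit$kinds, fit$levels)[mi, , drop = FALSE]
    Xs <- bayes_design(model, X)
    sigma2 <- model$rss / stats::rchisq(1L, model$df)
    beta_star <- model$beta + sqrt(sigma2) * drop(t(model$cholV) %*% stats::rnorm(length(model$beta)))
    yhat_new <- drop(Xs %*% beta_star)
    k <- min(spec$k_donors, length(model$y_obs))
    vapply(yhat_new, function(yh) {
      d <- abs(model$yhat_obs - yh)
      pool <- order(d)[seq_len(k)]
      model$y_obs[pool[sample.int(k, 1L)]]
    }, numeric(1))
  } else if (model$type == "lasso") {
    b <- model$boots[[min(imp_index, length(model$boots))]]
    X <- build_design(filled, model$others, fit$kinds, fit$levels)[mi, , drop = FALSE]
    pred <- if (is.null(b$beta)) rep(b$a0, n_mi) else drop(X %*% b$beta) + b$a0
    pred + stats::rnorm(n_mi, 0, b$sigma)
  } else stop("unknown model type")
}

#' Apply a fitted imputer to new rows
#'
#' Fills every missing cell of `rows` using training-set state only (LOCF
#' leaves leading gaps missing unless its mean fallback is enabled; the
#' `none` method fills nothing). Stochastic methods produce `m` completed
#' copies plus their cell-wise average; deterministic methods produce one.
#' Single-row application is supported.
#'
#' @param fitted a `gb_fitted_imputer`.
#' @param rows new rows sharing the training column contract (LOCF
#'   additionally requires `event_id` and `window_index`).
#' @param m number of imputations (default: the spec's `m`).
#' @param seed seed for the draws.
#' @return a `gb_imputed_bundle`: list with `imputations` (list of data
#'   frames), `average`, `m`, `method`, and `cell_mask` (logical matrix over
#'   feature columns, TRUE where the cell was originally missing).
#' @export
apply_imputer <- function(fitted, rows, m = NULL, seed = fitted$spec$seed + 1L) {
  stopifnot(inherits(fitted, "gb_fitted_imputer"))
  spec <- fitted$spec
  m <- m %||% spec$m
  if (is_deterministic_method(fitted$method)) m <- 1L
  missing_cols <- setdiff(fitted$cols, names(rows))
  if (length(missing_cols) > 0)
    stop("rows lack training columns: ", paste(missing_cols, collapse = ", "))

  ## unseen categorical levels map to the training mode
  for (v in fitted$cols[fitted$kinds == "categorical"]) {
    x <- as.character(rows[[v]])
    bad <- !is.na(x) & !(x %in% fitted$levels[[v]])
    if (any(bad)) {
      message(sprintf("%d unseen level(s) of '%s' mapped to training mode", sum(bad), v))
      x[bad] <- fitted$modes[[v]]
    }
    rows[[v]] <- factor(x, levels = fitted$levels[[v]])
  }

  cell_mask <- vapply(fitted$cols, function(v) is.na(rows[[v]]),
                      logical(nrow(rows)))
  if (nrow(rows) == 1L) cell_mask <- matrix(cell_mask, nrow = 1,
                                            dimnames = list(NULL, fitted$cols))
  set.seed(seed)

  imputations <- switch(
    fitted$method,
    none = list(rows),
    mean = list(init_fill(rows, fitted)),
    locf = list(locf_apply(fitted, rows)),
    {
      lapply(seq_len(m), function(j) chained_apply(fitted, rows, imp_index = j))
    })

  bundle <- list(imputations = imputations,
                 average = average_imputations_list(imputations, fitted),
                 m = length(imputations), method = fitted$method,
                 cell_mask = cell_mask)
  class(bundle) <- "gb_imputed_bundle"
  bundle
}

chained_apply <- function(fitted, rows, imp_index) {
  spec <- fitted$spec
  filled <- init_fill(rows, fitted)
  miss <- lapply(fitted$cols, function(v) which(is.na(rows[[v]])))
  names(miss) <- fitted$cols
  for (it in seq_len(spec$chained_iters)) {
    for (v in fitted$visit) {
      mi <- miss[[v]]
      if (length(mi) == 0L) next
      filled[[v]][mi] <- draw_var(spec, fitted$models[[v]], v, filled, mi,
                                  fitted, imp_index = imp_index)
    }
  }
  filled
}

#' Last observation carried forward
#'
#' Fills each missing cell of a within-event series with the most recent
#' prior observed value; values are carried forward indefinitely, future
#' values are never used, and leading gaps remain missing.
#'
#' @param x a series in window order (numeric or factor).
#' @return the series after carry-forward.
#' @export
locf_impute <- function(x) {
  obs <- !is.na(x)
  if (!any(obs) || all(obs)) return(x)
  last_obs <- cumsum(obs)          # index (among observed) of last prior value
  pos <- which(obs)
  fillable <- !obs & last_obs > 0  # leading gaps have last_obs == 0
  x[fillable] <- x[pos[last_obs[fillable]]]
  x
}

locf_apply <- function(fitted, rows) {
  if (!all(c("event_id", "window_index") %in% names(rows)))
    stop("LOCF requires event_id and window_index columns")
  ord <- order(rows$event_id, rows$window_index)
  inv <- order(ord)
  ev <- rows$event_id[ord]
  for (v in fitted$cols) {
    x <- rows[[v]][ord]
    pieces <- split(x, ev)
    x <- unsplit(lapply(pieces, locf_impute), ev)
    if (fitted$spec$locf_fallback == "mean") {
      idx <- is.na(x)
      if (any(idx)) {
        if (fitted$kinds[[v]] == "categorical") x[idx] <- fitted$modes[[v]]
        else x[idx] <- fitted$means[[v]]
      }
    }
    rows[[v]][ord] <- x
  }
  rows
}

average_imputations_list <- function(imputations, fitted) {
  if (length(imputations) == 1L) return(imputations[[1]])
  avg <- imputations[[1]]
  for (v in fitted$cols) {
    if (fitted$kinds[[v]] == "categorical") {
      levs <- fitted$levels[[v]]
      counts <- sapply(imputations, function(d) as.integer(d[[v]]))
      avg[[v]] <- factor(levs[apply(counts, 1, function(r) {
        if (all(is.na(r))) return(NA_integer_)
        tab <- tabulate(r, nbins = length(levs))
        which.max(tab)
      })], levels = levs)
    } else {
      vals <- sapply(imputations, function(d) d[[v]])
      avg[[v]] <- rowMeans(matrix(vals, nrow = nrow(avg)))
    }
  }
  avg
}

#' Average the imputations of a bundle
#'
#' Numeric and binary cells average arithmetically across the m completed
#' copies; categorical cells take the per-cell mode (ties resolved to the
#' earliest level). Observed cells are identical across copies and pass
#' through untouched.
#'
#' @param bundle a `gb_imputed_bundle`.
#' @return a single completed data frame.
#' @export
average_imputations <- function(bundle) {
  stopifnot(inherits(bundle, "gb_imputed_bundle"))
  bundle$average
}

#' @export
print.gb_fitted_imputer <- function(x, ...) {
  cat(sprintf("Fitted '%s' imputer: %d feature columns, %d training rows\n",
              x$method, length(x$cols), x$n_train))
  invisible(x)
}
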