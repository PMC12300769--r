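#' Tree-ensemble model harness
#'
#' Four regressors are supported, named for the boosting style their search
#' space emulates: `"catboost_like"` (depthwise growth, moderate depth,
#' strong L2 regularization), `"lightgbm_like"` (leaf-wise "lossguide" growth
#' controlled by `max_leaves`, with a conditional dart branch),
#' `"xgboost_like"` (classic depthwise gradient boosting), all backed by the
#' xgboost engine, and `"random_forest"` (ranger). The package's contribution
#' is the tuning/evaluation protocol, not the boosting internals.
#'
#' @name models
NULL

sdml_model_names <- c("catboost_like", "lightgbm_like", "xgboost_like", "random_forest")

model_space <- function(model_name) {
  common <- list(
    param_loguniform("eta", 1e-3, 0.3),
    param_uniform("subsample", 0.5, 1),
    param_uniform("colsample_bytree", 0.5, 1),
    param_int("nrounds", 50, 400)
  )
  switch(model_name,
    xgboost_like = c(common, list(
      param_int("max_depth", 3, 10),
      param_loguniform("min_child_weight", 0.1, 10),
      param_loguniform("lambda", 0.01, 10)
    )),
    lightgbm_like = c(common, list(
      param_int("max_leaves", 8, 128),
      param_loguniform("min_child_weight", 0.1, 10),
      param_categorical("booster", c("gbtree", "dart")),
      param_uniform("rate_drop", 0.0, 0.3,
                    condition = function(ps) identical(ps$booster, "dart"))
    )),
    catboost_like = c(common, list(
      param_int("max_depth", 4, 8),
      param_loguniform("lambda", 1, 30)
    )),
    random_forest = list(
      param_int("num_trees", 200, 800),
      param_uniform("mtry_frac", 0.2, 1),
      param_int("min_node_size", 1, 10),
      param_uniform("sample_fraction", 0.5, 1)
    ),
    stop("argument error: unknown model_name '", model_name, "'", call. = FALSE)
  )
}

default_params <- function(model_name) {
  switch(model_name,
    xgboost_like = list(eta = 0.1, subsample = 0.9, colsample_bytree = 1,
                        nrounds = 200, max_depth = 6, min_child_weight = 1, lambda = 1),
    lightgbm_like = list(eta = 0.1, subsample = 0.9, colsample_bytree = 1,
                         nrounds = 200, max_leaves = 31, min_child_weight = 1,
                         booster = "gbtree"),
    catboost_like = list(eta = 0.1, subsample = 0.9, colsample_bytree = 1,
                         nrounds = 200, max_depth = 6, lambda = 3),
    random_forest = list(num_trees = 500, mtry_frac = 1 / 3, min_node_size = 5,
                         sample_fraction = 1),
    stop("argument error: unknown model_name '", model_name, "'", call. = FALSE)
  )
}

model_matrix <- function(x) {
  feats <- feature_names(x)
  X <- as.matrix(as.data.frame(x)[, feats, drop = FALSE])
  storage.mode(X) <- "double"
  X
}

#' Fit a model with explicit parameters
#'
#' @param train A [feature_table()] with target.
#' @param model_name One of `"catboost_like"`, `"lightgbm_like"`,
#'   `"xgboost_like"`, `"random_forest"`.
#' @param params Named parameter list (defaults used for omissions).
#' @param seed Integer seed for the engine.
#' @return An `sdml_model` (supports [predict()] on feature tables).
#' @export
fit_model <- function(train, model_name, params = list(), seed = 1) {
  params <- utils::modifyList(default_params(model_name), params)
  X <- model_matrix(train)
  y <- target_values(train)
  fit <- if (model_name == "random_forest") {
    ranger::ranger(
      y = y, x = as.data.frame(X),
      num.trees = params$num_trees,
      mtry = max(1L, round(params$mtry_frac * ncol(X))),
      min.node.size = params$min_node_size,
      sample.fraction = params$sample_fraction,
      replace = TRUE, seed = seed, num.threads = 1
    )
  } else {
    xp <- list(objective = "reg:squarederror", nthread = 1, seed = seed,
               tree_method = "hist",
               eta = params$eta, subsample = params$subsample,
               colsample_bytree = params$colsample_bytree)
    if (model_name == "lightgbm_like") {
      xp$grow_policy <- "lossguide"
      xp$max_depth <- 0
      xp$max_leaves <- params$max_leaves
      xp$min_child_weight <- params$min_child_weight
      xp$booster <- params$booster
      if (identical(params$booster, "dart")) xp$rate_drop <- params$rate_drop
    } else {
      xp$max_depth <- params$max_depth
      xp$lambda <- params$lambda
      if (!is.null(params$min_child_weight)) xp$min_child_weight <- params$min_child_weight
    }
    dtrain <- xgboost::xgb.DMatrix(X, label = y)
    xgboost::xgb.train(params = xp, data = dtrain,
                       nrounds = params$nrounds, verbose = 0)
  }
  structure(list(model_name = model_name, fit = fit, params = params,
                 features = feature_names(train), target = target_name(train),
                 train = train, seed = seed),
            class = "sdml_model")
}

#' @export
predict.sdml_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "feature_table")) {
    as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  } else {
    as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  }
  storage.mode(X) <- "double"
  if (object$model_name == "random_forest") {
    stats::predict(object$fit, as.data.frame(X), num.threads = 1)$predictions
  } else {
    stats::predict(object$fit, xgboost::xgb.DMatrix(X))
  }
}

cv_folds <- function(n, n_folds, seed) {
  withr::with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
}

cv_metrics <- function(train, model_name, params, n_folds = 5, fold_id = NULL, seed = 1) {
  n <- nrow(train)
  if (is.null(fold_id)) fold_id <- cv_folds(n, n_folds, seed)
  rmse <- r2 <- numeric(n_folds)
  df <- as.data.frame(train)
  for (f in seq_len(n_folds)) {
    tr <- ft_replace(train, df[fold_id != f, , drop = FALSE])
    te <- ft_replace(train, df[fold_id == f, , drop = FALSE])
    m <- fit_model(tr, model_name, params, seed = seed + f)
    ev <- evaluate_model(m, te)
    rmse[f] <- ev["rmse"]; r2[f] <- ev["r2"]
  }
  c(cv_rmse = mean(rmse), cv_r2 = mean(r2))
}

#' Tune a model with TPE and refit on the full training set
#'
#' Runs a tree-structured Parzen estimator search over the model's space
#' (learning rate on a log scale, subsampling rates uniform, integer
#' depth/leaf ranges, with conditional branches skipping incompatible
#' combinations), scoring each configuration by mean `n_folds`-fold
#' cross-validated RMSE on fixed folds, then refits the incumbent on the full
#' training data.
#'
#' @param train A [feature_table()] with target.
#' @param model_name Model identifier (see [models]).
#' @param budget Number of TPE trials (>= 1; 1 degenerates to a single random
#'   draw).
#' @param n_folds Cross-validation folds (default 5).
#' @param seed Integer seed covering folds, search and final fit.
#' @return An `sdml_model` with extra fields `best_params`, `cv_rmse`,
#'   `cv_r2`, `n_trials`, `search_history`.
#' @export
tune_and_fit <- function(train, model_name, budget = 50, n_folds = 5, seed = 1) {
  if (!model_name %in% sdml_model_names) {
    stop("argument error: unknown model_name '", model_name, "'", call. = FALSE)
  }
  stopifnot(budget >= 1)
  fold_id <- cv_folds(nrow(train), n_folds, seed)
  objective <- function(ps) {
    unname(cv_metrics(train, model_name, ps, n_folds, fold_id, seed = seed)["cv_rmse"])
  }
  res <- tpe_optimize(model_space(model_name), objective, budget, seed = seed)
  cvm <- cv_metrics(train, model_name, res$best_params, n_folds, fold_id, seed = seed)
  model <- fit_model(train, model_name, res$best_params, seed = seed)
  model$best_params <- utils::modifyList(default_params(model_name), res$best_params)
  model$cv_rmse <- unname(cvm["cv_rmse"])
  model$cv_r2 <- unname(cvm["cv_r2"])
  model$n_trials <- budget
  model$search_history <- res$history
  sdml_log("tune_and_fit: %s, %d trials, best CV RMSE %.4f", model_name, budget, res$best_value)
  model
}

#' Evaluate a fitted model on a test table
#'
#' `R^2 = 1 - SS_res / SS_tot` and `RMSE = sqrt(mean((y - yhat)^2))`. A
#' zero-variance test target makes R^2 undefined; it is returned as `NA` with
#' a warning.
#'
#' @param model An `sdml_model` (or any object with a predict method taking
#'   the table).
#' @param test A [feature_table()] with target and the training columns.
#' @return Named vector `c(r2 = , rmse = )`.
#' @export
evaluate_model <- function(model, test) {
  y <- target_values(test)
  pred <- stats::predict(model, test)
  rmse <- sqrt(mean((y - pred)^2))
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot == 0) {
    warning("zero-variance test target: R^2 undefined")
    NA_real_
  } else 1 - sum((y - pred)^2) / sstot
  c(r2 = r2, rmse = rmse)
}

#' Compare paired original/augmented model reports
#'
#' Takes a data frame of model reports (columns `model_name`, `dataset` in
#' `{"original", "augmented"}`, `cv_r2`, `cv_rmse`, `test_r2`, `test_rmse`)
#' with exactly one original and one augmented row per model, and returns
#' per-model deltas and percent changes. Percent improvement for RMSE uses
#' the `(old - new) / old * 100` convention; for R^2, `(new - old) / old *
#' 100`.
#'
#' @param reports Data frame of paired reports.
#' @return Data frame, one row per model, with `*_delta` and
#'   `*_improvement_pct` columns.
#' @export
compare_runs <- function(reports) {
  need <- c("model_name", "dataset", "cv_r2", "cv_rmse", "test_r2", "test_rmse")
  stopifnot(all(need %in% names(reports)))
  out <- lapply(unique(reports$model_name), function(mn) {
    orig <- reports[reports$model_name == mn & reports$dataset == "original", ]
    aug <- reports[reports$model_name == mn & reports$dataset == "augmented", ]
    if (nrow(orig) != 1 || nrow(aug) != 1) {
      stop("pairing error: model '", mn, "' needs exactly one original and one augmented report",
           call. = FALSE)
    }
    data.frame(
      model_name = mn,
      cv_rmse_delta = aug$cv_rmse - orig$cv_rmse,
      cv_rmse_improvement_pct = (orig$cv_rmse - aug$cv_rmse) / orig$cv_rmse * 100,
      test_rmse_delta = aug$test_rmse - orig$test_rmse,
      test_rmse_improvement_pct = (orig$test_rmse - aug$test_rmse) / orig$test_rmse * 100,
      cv_r2_delta = aug$cv_r2 - orig$cv_r2,
      cv_r2_improvement_pct = (aug$cv_r2 - orig$cv_r2) / orig$cv_r2 * 100,
      test_r2_delta = aug$test_r2 - orig$test_r2,
      test_r2_improvement_pct = (aug$test_r2 - orig$test_r2) / orig$test_r2 * 100
    )
  })
  do.call(rbind, out)
}
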