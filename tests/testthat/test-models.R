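test_that("evaluation metrics match their definitions", {
  truth <- c(0, 1, 2)
  m_exact <- structure(list(), class = "const_model")
  tb <- feature_table(data.frame(x = 1:3, y = truth), target = "y")

  fake <- function(preds) {
    structure(list(preds = preds), class = "fake_model")
  }
  assign("predict.fake_model", function(object, newdata, ...) object$preds,
         envir = globalenv())
  withr::defer(rm("predict.fake_model", envir = globalenv()))

  ev <- evaluate_model(fake(truth), tb)
  expect_equal(unname(ev), c(1, 0))
  ev2 <- evaluate_model(fake(rep(mean(truth), 3)), tb)
  expect_equal(unname(ev2["r2"]), 0)
  ev3 <- evaluate_model(fake(c(0, 1, 1)), tb)
  expect_equal(unname(ev3["rmse"]), sqrt(1 / 3))

  flat <- feature_table(data.frame(x = 1:3, y = rep(1, 3)), target = "y")
  expect_warning(ev4 <- evaluate_model(fake(truth), flat), "zero-variance")
  expect_true(is.na(ev4["r2"]))
})

test_that("all four model engines learn a noiseless single-feature map", {
  tb <- withr::with_seed(3, {
    df <- data.frame(x1 = runif(200, -3, 3), x2 = runif(200))
    df$y <- df$x1
    feature_table(df, target = "y")
  })
  for (mn in c("catboost_like", "lightgbm_like", "xgboost_like", "random_forest")) {
    # with only 2 candidate features the forest needs the full feature view
    # per split (its default mtry of p/3 would blind half the splits)
    params <- if (mn == "random_forest") list(mtry_frac = 1, min_node_size = 1) else list()
    cvm <- sdml:::cv_metrics(tb, mn, params, n_folds = 5, seed = 1)
    expect_gt(cvm["cv_r2"], 0.99)
  }
  expect_error(fit_model(tb, "neural_net"), "argument")
})

test_that("model fits are reproducible under a fixed seed", {
  sp <- default_synth_train(n_total = 120, seed = 61)
  for (mn in c("xgboost_like", "random_forest")) {
    m1 <- fit_model(sp$train, mn, seed = 5)
    m2 <- fit_model(sp$train, mn, seed = 5)
    expect_identical(predict(m1, sp$test), predict(m2, sp$test))
  }
})

test_that("TPE improves over random sampling on a quadratic objective", {
  space <- list(param_uniform("a", -5, 5), param_loguniform("b", 0.01, 100))
  obj <- function(ps) (ps$a - 2)^2 + (log10(ps$b) - 1)^2
  res <- tpe_optimize(space, obj, budget = 60, seed = 1)
  expect_lt(res$best_value, 0.5)
  expect_equal(nrow(res$history), 60)
  # incumbent best is non-increasing in budget on the same seed
  res_small <- tpe_optimize(space, obj, budget = 15, seed = 1)
  expect_lte(res$best_value, res_small$best_value)
})

test_that("conditional parameters are sampled only when their branch is active", {
  space <- list(
    param_categorical("booster", c("gbtree", "dart")),
    param_uniform("rate_drop", 0, 0.3,
                  condition = function(ps) identical(ps$booster, "dart"))
  )
  res <- tpe_optimize(space, function(ps) {
    if (identical(ps$booster, "dart")) {
      expect_true(!is.null(ps$rate_drop))
      0.1 + ps$rate_drop
    } else {
      expect_null(ps$rate_drop)
      1
    }
  }, budget = 25, seed = 3)
  expect_equal(res$best_params$booster, "dart")
})

test_that("tune_and_fit returns CV metrics and beats a budget-1 draw", {
  sp <- default_synth_train(n_total = 120, seed = 71)
  m1 <- tune_and_fit(sp$train, "xgboost_like", budget = 1, n_folds = 3, seed = 2)
  expect_equal(m1$n_trials, 1)
  expect_true(is.finite(m1$cv_rmse))
  m8 <- tune_and_fit(sp$train, "xgboost_like", budget = 8, n_folds = 3, seed = 2)
  expect_lte(min(m8$search_history$value), min(m1$search_history$value))
  ev <- evaluate_model(m8, sp$test)
  expect_true(is.finite(ev["r2"]))
})

test_that("compare_runs reproduces printed percent improvements", {
  reports <- data.frame(
    model_name = rep("catboost_like", 2),
    dataset = c("original", "augmented"),
    cv_r2 = c(0.8224, 0.8564), cv_rmse = c(0.7401, 0.6906),
    test_r2 = c(0.8012, 0.8300), test_rmse = c(0.8015, 0.7401)
  )
  cmp <- compare_runs(reports)
  expect_equal(round(cmp$test_rmse_improvement_pct, 1), 7.7)
  expect_equal(round(cmp$cv_rmse_improvement_pct, 1), 6.7)

  same <- reports; same[2, 3:6] <- same[1, 3:6]
  cmp0 <- compare_runs(same)
  expect_true(all(abs(unlist(cmp0[, -1])) < 1e-12))

  expect_error(compare_runs(reports[1, ]), "pairing")
})
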