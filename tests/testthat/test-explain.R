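# a hand-built stump over 2 features: splits on x1 at 0, leaves -1 / +1,
# covers 10/10
stump_structure <- function() {
  tab <- data.frame(node = 1:3,
                    feature = c("x1", NA, NA),
                    split = c(0, NA, NA),
                    yes = c(2L, NA, NA), no = c(3L, NA, NA),
                    value = c(NA, -1, 1),
                    cover = c(20, 10, 10), stringsAsFactors = FALSE)
  structure(list(trees = list(tab), base = 0, le = FALSE,
                 features = c("x1", "x2")),
            class = "tree_structure")
}

test_that("unused features receive exactly zero attribution (null player)", {
  ts <- stump_structure()
  data <- data.frame(x1 = c(-2, 3, 0.5), x2 = c(10, -10, 0))
  ex <- explain_model(ts, data, tier = "tree")
  expect_identical(unname(ex$shap_values[, "x2"]), c(0, 0, 0))
  expect_equal(ex$base_value, 0)  # balanced covers: E = 0
  expect_equal(unname(ex$shap_values[, "x1"]), c(-1, 1, 1))
})

test_that("tree-tier attributions are additive for both engines", {
  sp <- default_synth_train(n_total = 120, seed = 41)
  test10 <- sp$test[1:10, ]

  mx <- fit_model(sp$train, "xgboost_like",
                  list(nrounds = 40, max_depth = 3), seed = 1)
  ex <- explain_model(mx, test10, tier = "tree")
  expect_equal(ex$tier_used, "tree")
  # xgboost stores the model in single precision; additivity holds to that
  # resolution (the tree-tier game itself is exact, see the forest case)
  expect_lt(max(abs(ex$base_value + rowSums(ex$shap_values) - predict(mx, test10))), 4e-6)

  mr <- fit_model(sp$train, "random_forest", list(num_trees = 20), seed = 1)
  exr <- explain_model(mr, test10)
  expect_equal(exr$tier_used, "tree")  # no native attribution for forests
  expect_lt(max(abs(exr$base_value + rowSums(exr$shap_values) - predict(mr, test10))), 1e-9)
})

test_that("the native tier is used for boosted models and is additive", {
  sp <- default_synth_train(n_total = 120, seed = 42)
  m <- fit_model(sp$train, "xgboost_like", list(nrounds = 40), seed = 1)
  ex <- explain_model(m, sp$test)
  expect_equal(ex$tier_used, "native")
  expect_lt(max(abs(ex$base_value + rowSums(ex$shap_values) - predict(m, sp$test))), 2e-6)
})

test_that("constant predictions yield all-zero attributions", {
  tab <- data.frame(node = 1L, feature = NA_character_, split = NA_real_,
                    yes = NA_integer_, no = NA_integer_, value = 5, cover = 10,
                    stringsAsFactors = FALSE)
  ts <- structure(list(trees = list(tab), base = 0, le = FALSE,
                       features = c("x1", "x2")), class = "tree_structure")
  ex <- explain_model(ts, data.frame(x1 = 1:3, x2 = 4:6), tier = "tree")
  expect_true(all(ex$shap_values == 0))
  expect_equal(ex$base_value, 5)
})

test_that("kernel tier is additive and nearly symmetric on duplicated features", {
  tb <- withr::with_seed(7, {
    df <- data.frame(x1 = runif(80, -2, 2))
    df$x2 <- df$x1  # exchangeable duplicate
    df$x3 <- runif(80, -2, 2)
    df$y <- df$x1 + df$x2 + df$x3 + rnorm(80, 0, 0.05)
    feature_table(df, target = "y")
  })
  m <- fit_model(tb, "random_forest", list(num_trees = 50), seed = 2)
  ex <- explain_model(m, tb[1:15, ], tier = "kernel")
  expect_equal(ex$tier_used, "kernel")
  pr <- predict(m, tb[1:15, ])
  expect_lt(max(abs(ex$base_value + rowSums(ex$shap_values) - pr)), 1e-2)
  imp <- colMeans(abs(ex$shap_values))
  imp <- imp / sum(imp)
  expect_lt(abs(imp["x1"] - imp["x2"]), 0.05)
})

test_that("cross-model importance ranks a planted dominant effect first", {
  tb <- withr::with_seed(9, {
    df <- data.frame(x1 = runif(150, -2, 2), x2 = runif(150, -2, 2))
    df$y <- 5 * df$x1 + df$x2 + rnorm(150, 0, 0.1)
    feature_table(df, target = "y")
  })
  exps <- list()
  for (mn in c("xgboost_like", "catboost_like", "random_forest")) {
    m <- fit_model(tb, mn, list(nrounds = 60, num_trees = 60), seed = 1)
    exps[[mn]] <- explain_model(m, tb[1:30, ])
  }
  tabr <- rank_importance(exps)
  expect_equal(tabr$feature[1], "x1")
  for (mn in names(exps)) {
    expect_equal(sum(tabr[[mn]]), 1, tolerance = 1e-9)
    expect_gt(tabr[[mn]][tabr$feature == "x1"], tabr[[mn]][tabr$feature == "x2"])
  }
  # mismatched feature sets are rejected
  bad <- exps
  colnames(bad[[1]]$shap_values) <- c("a", "b")
  expect_error(rank_importance(bad), "alignment")
})
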