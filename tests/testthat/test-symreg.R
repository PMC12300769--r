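term_labels <- function(eq) {
  vapply(eq$terms, function(tm)
    paste(vapply(tm$factors, sdml:::factor_label, character(1)), collapse = "*"),
    character(1))
}

test_that("equations evaluate, serialize and round-trip exactly", {
  eq <- equation(
    terms = list(sdml:::eq_term(2, list("x1")),
                 sdml:::eq_term(-1.5, list("x2"), list("x3")),
                 sdml:::eq_term(0.3, list("x1", 2, "sqrt_abs"))),
    intercept = 0.7, method = "manual")
  df <- withr::with_seed(1, data.frame(x1 = rnorm(20), x2 = rnorm(20), x3 = rnorm(20)))
  pred <- evaluate_equation(eq, df)$predictions
  expect_equal(pred, 0.7 + 2 * df$x1 - 1.5 * df$x2 * df$x3 + 0.3 * abs(df$x1),
               tolerance = 1e-12)
  back <- eq_parse(eq_serialize(eq))
  expect_equal(evaluate_equation(back, df)$predictions, pred, tolerance = 1e-12)

  # intercept-only
  const <- equation(intercept = 3)
  expect_equal(evaluate_equation(const, df)$predictions, rep(3, 20))
  # missing feature is named in the error
  expect_error(evaluate_equation(eq, df[, 1:2]), "x3")
})

test_that("example equations evaluate finitely under protected operators", {
  eqs <- example_equations()
  grid <- expand.grid(MW = c(0, 500, 714), logKow = c(-2, 0, 7), pKa = c(-1, 0, 5))
  for (eq in eqs) {
    v <- evaluate_equation(eq, grid)$predictions
    expect_true(all(is.finite(v)))
    back <- eq_parse(eq_serialize(eq))
    expect_equal(evaluate_equation(back, grid)$predictions, v, tolerance = 1e-12)
  }
})

test_that("GP recovers an exact additive law in most seeded runs", {
  hits <- vapply(1:10, function(seed) {
    tb <- withr::with_seed(seed + 100, {
      df <- data.frame(x1 = runif(60, -3, 3), x2 = runif(60, -3, 3))
      df$y <- df$x1 + df$x2
      feature_table(df, target = "y")
    })
    eq <- fit_gp(tb, pop = 500, gens = 20, seed = seed)
    eq$train_rmse < 1e-6
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("GP with zero generations still returns a finite incumbent", {
  tb <- linear_fixture(n = 60, seed = 5)
  eq <- fit_gp(tb, pop = 80, gens = 0, seed = 2)
  expect_true(is.finite(eq$train_rmse))
  expect_true(all(is.finite(evaluate_equation(eq, tb)$predictions)))
  # the default configuration records the full published budget
  expect_equal(formals(fit_gp)$pop, 2000)
  expect_equal(formals(fit_gp)$gens, 100)
})

test_that("MFTEC recovers a planted transform and flattens exactly", {
  tb <- withr::with_seed(12, {
    df <- data.frame(x1 = runif(150, 0, 4), x2 = runif(150, -2, 2))
    df$y <- 2 * sqrt(abs(df$x1)) + rnorm(150, 0, 0.05)
    feature_table(df, target = "y")
  })
  sc <- score_features(tb, n_bootstrap = 5, seed = 1)
  eq <- fit_mftec(tb, sc, m = 2)
  labs <- term_labels(eq)
  X <- as.data.frame(tb)
  contrib <- vapply(eq$terms, function(tm)
    abs(tm$coef) * stats::sd(sdml:::term_column(X, tm$factors)), numeric(1))
  expect_equal(labs[which.max(contrib)], "sqrt_abs(x1)")
  # flattened equation reproduces the stacked pipeline exactly
  expect_lt(max(abs(evaluate_equation(eq, tb)$predictions - attr(eq, "pipeline_pred"))), 1e-8)

  # constant target collapses to an intercept
  flat <- feature_table(data.frame(x1 = runif(50), x2 = runif(50), y = rep(2, 50)),
                        target = "y")
  scf <- data.frame(feature = c("x1", "x2"), composite = c(0, 0))
  class(scf) <- c("feature_scores", "data.frame")
  eqf <- fit_mftec(flat, scf, m = 2)
  expect_equal(eqf$intercept, 2)
  expect_true(all(vapply(eqf$terms, function(tm) abs(tm$coef), numeric(1)) < 1e-6))
  expect_error(fit_mftec(tb, sc, m = 0), "argument")
})

test_that("HSIE recovers planted sparse interactions and monomials", {
  df <- withr::with_seed(3, {
    n <- 500
    X <- data.frame(x1 = runif(n, -2, 2), x2 = runif(n, -2, 2),
                    x3 = runif(n, -2, 2), x4 = runif(n, -2, 2))
    X$y <- 2 * X$x1 - 1.5 * X$x2 * X$x3 + rnorm(n, 0, 0.1)
    X
  })
  eq <- fit_hsie(feature_table(df, target = "y"), max_order = 3, seed = 1)
  labs <- term_labels(eq)
  expect_true(all(c("x1", "x2*x3") %in% labs))
  cf <- vapply(eq$terms, `[[`, numeric(1), "coef")
  expect_equal(cf[labs == "x1"], 2, tolerance = 0.05)
  expect_equal(cf[labs == "x2*x3"], -1.5, tolerance = 0.05)
  expect_true(all(abs(cf[!labs %in% c("x1", "x2*x3")]) <= 0.2))

  # pure cubic, noiseless
  dfc <- withr::with_seed(4, data.frame(x1 = runif(100, -2, 2)))
  dfc$y <- dfc$x1^3
  eqc <- fit_hsie(feature_table(dfc, target = "y"), max_order = 3, seed = 1)
  expect_equal(term_labels(eqc), "x1^3")
  expect_equal(eqc$terms[[1]]$coef, 1, tolerance = 0.01)

  # reported fit R^2 is self-consistent with re-evaluation
  expect_equal(evaluate_equation(eq, feature_table(df, target = "y"))$r2,
               eq$fit_r2, tolerance = 1e-10)
})

test_that("HSIE with max_order 1 reduces to ordinary least squares", {
  tb <- linear_fixture(n = 80, seed = 21)
  eq <- fit_hsie(tb, max_order = 1, seed = 1)
  ols <- lm(y ~ x1 + x2 + x3, data = as.data.frame(tb))
  labs <- term_labels(eq)
  cf <- vapply(eq$terms, `[[`, numeric(1), "coef")
  expect_equal(eq$intercept, unname(coef(ols)[1]), tolerance = 1e-6)
  for (f in c("x1", "x2", "x3")) {
    expect_equal(unname(cf[labs == f]), unname(coef(ols)[f]), tolerance = 1e-6)
  }
  # dictionary overflow guard
  wide <- withr::with_seed(5, as.data.frame(matrix(runif(50 * 45), 50)))
  wide$y <- runif(50)
  expect_error(fit_hsie(feature_table(wide, target = "y"), max_order = 3,
                        dict_cap = 500), "overflow")
})
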