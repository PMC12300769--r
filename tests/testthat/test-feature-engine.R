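test_that("derived composite features follow their closed forms", {
  df <- data.frame(MW = c(100, 500, 200), logKow = c(0, 2, -1),
                   pKa = c(1, 2, 3), TPSA = c(50, 0, 30),
                   ExposureTime = c(0, 10, 1e6), y = c(1, 2, 3))
  tb <- derive_features(feature_table(df, target = "y"))
  # TPSA = 50, MW = 100, logKow = 0 -> 50 / (100 * 1) = 0.5
  expect_equal(tb$water_solubility_index[1], 0.5)
  # zero numerator
  expect_equal(tb$water_solubility_index[2], 0)
  # saturating kinetics: 0 at t = 0, -> 1 for large t, monotone
  expect_equal(tb$absorption_kinetics[1], 0)
  expect_gt(tb$absorption_kinetics[3], 1 - 1e-6)
  expect_true(all(diff(tb$absorption_kinetics[c(1, 2, 3)]) > 0))
  expect_equal(tb$absorption_kinetics[2], 1 - exp(-0.05))
  # near-zero denominator is flagged as missing
  df2 <- data.frame(MW = 1, logKow = -2, pKa = 0, TPSA = 10,
                    ExposureTime = 1, y = 0)
  tb2 <- derive_features(feature_table(df2, target = "y"))
  expect_true(is.na(tb2$water_solubility_index[1]))
  # default base set appends 27 derived columns
  expect_equal(length(feature_names(tb)) - 5, 27)
})

test_that("informative features outscore noise and duplicates are penalized", {
  tb <- withr::with_seed(31, {
    n <- 150
    df <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
    df$y <- 3 * df$x1 + rnorm(n, 0, 0.01)
    feature_table(df, target = "y")
  })
  sc <- score_features(tb, n_bootstrap = 10, seed = 1)
  expect_gt(sc$composite[sc$feature == "x1"], sc$composite[sc$feature == "x2"])
  expect_true(all(sc$composite >= 0 & sc$composite <= 1))
  expect_true(all(sc$stability >= 0 & sc$stability <= 1))

  # exact duplicate drives VIF to infinity and the composite to 0
  df2 <- as.data.frame(tb)
  df2$x1_dup <- df2$x1
  sc2 <- score_features(feature_table(df2, target = "y"), n_bootstrap = 5, seed = 1)
  expect_false(is.finite(sc2$vif[sc2$feature == "x1"]))
  expect_equal(sc2$composite[sc2$feature %in% c("x1", "x1_dup")], c(0, 0))
  expect_true(all(sc2$flagged[sc2$feature %in% c("x1", "x1_dup")]))

  # constant feature: zero composite, flagged
  df3 <- as.data.frame(tb)
  df3$const <- 1
  sc3 <- score_features(feature_table(df3, target = "y"), n_bootstrap = 5, seed = 1)
  expect_equal(sc3$composite[sc3$feature == "const"], 0)
})

test_that("with all weight on the F-statistic, ranking matches squared correlation", {
  tb <- withr::with_seed(17, {
    n <- 200
    df <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
    df$y <- 2 * df$a + 1 * df$b + 0.3 * df$c + rnorm(n, 0, 0.5)
    feature_table(df, target = "y")
  })
  sc <- score_features(tb, n_bootstrap = 0,
                       weights = c(f_stat = 1, mutual_info = 0, dist_corr = 0,
                                   mic = 0, relieff = 0), seed = 1)
  r2 <- vapply(c("a", "b", "c"), function(f) cor(tb[[f]], tb$y)^2, numeric(1))
  expect_identical(sc$feature, names(sort(r2, decreasing = TRUE)))
})

test_that("composite scores are invariant to affine rescaling of a feature", {
  tb <- recovery_fixture(seed = 5, n = 120, n_inf = 2, n_noise = 3)
  sc1 <- score_features(tb, n_bootstrap = 5, seed = 2)
  df <- as.data.frame(tb)
  df$inf1 <- df$inf1 * 1000 + 50
  sc2 <- score_features(feature_table(df, target = "y"), n_bootstrap = 5, seed = 2)
  s1 <- sc1$composite[match(sc1$feature, sc1$feature)]
  expect_equal(sc2$composite[match(sc1$feature, sc2$feature)],
               sc1$composite, tolerance = 1e-6)
})

test_that("top-k selection is deterministic with lexicographic ties", {
  sc <- data.frame(feature = c("b", "a", "c"), composite = c(0.9, 0.5, 0.5))
  class(sc) <- c("feature_scores", "data.frame")
  # score_features orders ties by name already; emulate its invariant here
  sc <- sc[order(-sc$composite, sc$feature), ]
  expect_equal(select_features(sc, 3), c("b", "a", "c"))
  expect_equal(select_features(sc, 2), c("b", "a"))
  expect_error(select_features(sc, 0), "argument")
  expect_error(select_features(sc, 9), "argument")
})
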