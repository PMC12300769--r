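test_that("imputation is an identity on complete tables and recovers structure", {
  ft <- linear_fixture(n = 80, seed = 2)
  res <- impute_missing(ft, seed = 1)
  expect_equal(as.data.frame(res$table), as.data.frame(ft))
  expect_true(all(res$report$n_imputed == 0))

  # y2 = 2 * x: a masked cell must be recovered within 10%
  df <- withr::with_seed(4, data.frame(x = runif(60, 1, 10)))
  df$y2 <- 2 * df$x
  df$target <- df$x + rnorm(60, 0, 0.01)
  truth <- df$y2[7]
  df$y2[7] <- NA
  tb <- feature_table(df, target = "target")
  imp <- impute_missing(tb, seed = 9)
  expect_lt(abs(imp$table$y2[7] - truth) / truth, 0.1)

  # determinism under a fixed seed
  imp2 <- impute_missing(tb, seed = 9)
  expect_identical(imp$table$y2[7], imp2$table$y2[7])

  df$y2 <- NA_real_
  expect_error(impute_missing(feature_table(df, target = "target")), "unimputable")
})

test_that("1.5-IQR trimming matches a brute-force quartile oracle", {
  sym <- feature_table(data.frame(x = 1:9, y = as.numeric(1:9)), target = "y")
  expect_equal(nrow(trim_outliers(sym)$table), 9)

  out <- feature_table(data.frame(x = 1:5, y = c(1, 2, 3, 4, 100)), target = "y")
  trimmed <- trim_outliers(out)
  expect_equal(trimmed$table$y, c(1, 2, 3, 4))
  # oracle: type-7 quartiles by hand
  q1 <- as.numeric(quantile(c(1, 2, 3, 4, 100), 0.25, type = 7))
  q3 <- as.numeric(quantile(c(1, 2, 3, 4, 100), 0.75, type = 7))
  expect_equal(trimmed$bounds, c(lower = q1 - 1.5 * (q3 - q1), upper = q3 + 1.5 * (q3 - q1)))

  flat <- feature_table(data.frame(x = 1:6, y = rep(2, 6)), target = "y")
  expect_equal(nrow(trim_outliers(flat)$table), 6)  # IQR = 0: nothing outside [Q1, Q3]
  expect_error(trim_outliers(out[1:3, ]), "nsufficient")
})

test_that("re-trimming after removals can remove more rows", {
  y <- c(rep(1, 10), 3, 8, 40)
  tb <- feature_table(data.frame(x = seq_along(y), y = y), target = "y")
  first <- trim_outliers(tb)
  expect_lt(nrow(first$table), nrow(tb))
  second <- trim_outliers(first$table)
  expect_lte(nrow(second$table), nrow(first$table))
})

test_that("skewness-gated log transform symmetrizes heavy-tailed columns", {
  sym <- withr::with_seed(1, data.frame(a = rnorm(300), y = rnorm(300)))
  tbs <- feature_table(sym, target = "y")
  res <- transform_skewed(tbs, skew_threshold = 1)
  expect_equal(res$table$a, sym$a)  # symmetric column untouched

  ln <- withr::with_seed(2, data.frame(a = exp(rnorm(300, 0, 1)), y = rnorm(300)))
  tbl <- feature_table(ln, target = "y")
  before <- skewness(ln$a)
  expect_gt(before, 1)  # log-normal draw is positively skewed by construction
  res2 <- transform_skewed(tbl, skew_threshold = 1)
  expect_equal(res2$report$transform_applied[res2$report$column == "a"], "log10")
  expect_lt(abs(skewness(res2$table$a)), before)

  res3 <- transform_skewed(tbl, skew_threshold = Inf)
  expect_equal(as.data.frame(res3$table), ln)  # infinite threshold: identity
})

test_that("categorical encoding assigns first-appearance codes and inverts", {
  df <- data.frame(species = c("lettuce", "maize", "lettuce", "wheat"),
                   y = c(1, 2, 3, 4), stringsAsFactors = FALSE)
  tb <- feature_table(df, target = "y", kinds = c(species = "categorical"))
  enc <- encode_categories(tb)
  expect_equal(enc$table$species, c(0, 1, 0, 2))
  expect_equal(decode_categories(enc$table, enc$mapping)$species, df$species)

  already <- feature_table(data.frame(species = c(2L, 0L, 1L), y = 1:3),
                           target = "y", kinds = c(species = "categorical"))
  expect_equal(encode_categories(already)$table$species, c(2L, 0L, 1L))
})

test_that("pipeline row counts reconcile across stages", {
  sim <- simulate_dataset(generator_spec(n = 90, seed = 13, missing_rate = 0.05))
  res <- preprocess(sim$table, seed = 1)
  n_trimmed <- sum(res$reports$trim$n_trimmed)
  expect_equal(nrow(res$table), nrow(sim$table) - n_trimmed)
  expect_false(anyNA(as.data.frame(res$table)))
})
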