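test_that("adaptive bin count follows max(6, min(12, floor(n/12)))", {
  expect_equal(make_bins(rnorm(462))$n_bins, 12)
  expect_equal(make_bins(withr::with_seed(1, rnorm(60)))$n_bins, 6)
  expect_equal(make_bins(withr::with_seed(1, rnorm(24)))$n_bins, 6)
  expect_equal(make_bins(withr::with_seed(1, rnorm(120)))$n_bins, 10)
  expect_error(make_bins(rnorm(23)), "nsufficient")
})

test_that("binning strategy switches on skewness and stats cover the sample", {
  sym <- withr::with_seed(2, rnorm(100))
  b1 <- make_bins(sym)
  expect_equal(b1$strategy, "equal_width")
  expect_equal(diff(range(diff(b1$edges))), 0, tolerance = 1e-12)

  skw <- withr::with_seed(3, exp(rnorm(100)))
  b2 <- make_bins(skw)
  expect_equal(b2$strategy, "equal_frequency")
  expect_equal(sum(b2$stats$n_samples), 100)
  expect_equal(min(b2$edges), min(skw))
  expect_equal(max(b2$edges), max(skw))
})

test_that("quota planning apportions the deficit by largest remainder", {
  y <- withr::with_seed(4, rnorm(60))
  b <- make_bins(y)
  # expansion 1: nothing to generate
  expect_true(all(plan_quotas(b, 1)$quota == 0))

  # hand-built two-bin-style check through a brute-force oracle
  b3 <- b
  b3$stats$n_samples <- c(30, 10, 20, 0, 0, 0)[seq_len(b$n_bins)]
  b3$n_train <- sum(b3$stats$n_samples)
  q <- plan_quotas(b3, 2)$quota
  expect_equal(sum(q), 60)
  # brute-force largest-remainder apportionment over deficit + 1 weights
  w <- (max(b3$stats$n_samples) - b3$stats$n_samples) + 1
  shares <- 60 * w / sum(w)
  base <- floor(shares); rem <- 60 - sum(base)
  base[order(-(shares - base), seq_along(shares))[seq_len(rem)]] <-
    base[order(-(shares - base), seq_along(shares))[seq_len(rem)]] + 1
  expect_equal(q, as.integer(base))
  # the sparsest populated bin receives the largest quota among populated bins
  expect_equal(which.max(q[1:3]), 2L)
})

test_that("symmetric two-bin deficits split the quota evenly", {
  y <- c(withr::with_seed(5, runif(12, 0, 1)), withr::with_seed(6, runif(12, 9, 10)))
  b <- make_bins(y)  # 6 equal-width bins; only the outer bins are occupied
  b <- plan_quotas(b, 2)
  occ <- b$stats$n_samples > 0
  expect_equal(sum(b$quota), 24)
  expect_equal(b$quota[1], b$quota[b$n_bins])
})

test_that("SMOTER replay oracle: zero-noise samples lie exactly on logged segments", {
  sp <- default_synth_train()
  train <- sp$train
  bins <- plan_quotas(make_bins(target_values(train)), 2)
  syn <- smote_generate(train, bins, k_neighbors = 5, noise_scale = 0, n = 120, seed = 42)
  draws <- attr(syn, "draws")
  expect_equal(nrow(draws), 120)
  df <- as.data.frame(train)
  cont <- setdiff(feature_names(train), "species")
  for (r in seq_len(nrow(draws))) {
    xi <- as.numeric(df[draws$i[r], cont])
    xnn <- as.numeric(df[draws$nn[r], cont])
    expected <- xi + draws$mu[r] * (xnn - xi)
    expect_equal(as.numeric(as.data.frame(syn)[r, cont]), expected, tolerance = 1e-12)
    # target interpolates with the same mu
    yi <- df$logRCF[draws$i[r]]; ynn <- df$logRCF[draws$nn[r]]
    expect_equal(syn$logRCF[r], yi + draws$mu[r] * (ynn - yi), tolerance = 1e-12)
    # categorical copied from the seed row
    expect_equal(syn$species[r], df$species[draws$i[r]])
  }
  # donor and neighbour share the seed's bin
  yb <- sdml:::bin_assign(bins$edges, df$logRCF)
  expect_true(all(yb[draws$i] == draws$bin & yb[draws$nn] == draws$bin))
})

test_that("SMOTER endpoints reproduce the interpolation formula limits", {
  sp <- default_synth_train(n_total = 80, seed = 77)
  train <- sp$train
  bins <- plan_quotas(make_bins(target_values(train)), 2)
  syn <- smote_generate(train, bins, noise_scale = 0.3, n = 40, seed = 9)
  delta <- attr(syn, "delta")
  draws <- attr(syn, "draws")
  df <- as.data.frame(train)
  cont <- colnames(delta)
  # subtracting the logged delta recovers the mu-interpolation exactly
  for (r in c(1, 20, 40)) {
    xi <- as.numeric(df[draws$i[r], cont])
    xnn <- as.numeric(df[draws$nn[r], cont])
    expect_equal(unname(as.numeric(as.data.frame(syn)[r, cont]) - delta[r, ]),
                 xi + draws$mu[r] * (xnn - xi), tolerance = 1e-10)
  }
})

test_that("VAE training reduces loss, is seed-deterministic, and handles edge cases", {
  sp <- default_synth_train(n_total = 120, seed = 21)
  st <- vae_fit(sp$train, epochs = 40, seed = 5)
  expect_lt(st$losses[40], st$losses[1])
  st2 <- vae_fit(sp$train, epochs = 40, seed = 5)
  expect_identical(st$losses, st2$losses)

  # untrained state still samples finite vectors from the prior
  st0 <- vae_fit(sp$train, epochs = 0, seed = 1)
  b <- plan_quotas(make_bins(target_values(sp$train)), 2)
  g0 <- vae_generate(st0, b, 10, seed = 2, margin = 10)
  expect_true(all(is.finite(as.matrix(as.data.frame(g0)))))

  # point-mass data standardizes to all zeros; prior decodes converge to 0
  df <- as.data.frame(sp$train)[rep(1, 60), ]
  pm <- feature_table(df, target = "logRCF", kinds = column_kinds(sp$train))
  stp <- vae_fit(pm, epochs = 150, seed = 3)
  Z <- withr::with_seed(4, matrix(rnorm(50 * stp$latent_dim), 50))
  dec <- sdml:::vae_decode(stp, Z)
  expect_lt(mean(abs(dec)), 0.15)
})

test_that("VAE samples respect the target envelope and match the prior moments", {
  df <- withr::with_seed(8, data.frame(a = rnorm(400), b = rnorm(400)))
  df$y <- withr::with_seed(9, rnorm(400))
  tb <- feature_table(df, target = "y")
  st <- vae_fit(tb, epochs = 120, seed = 11)
  bins <- make_bins(df$y)
  g <- vae_generate(st, bins, 1000, seed = 12)
  expect_equal(nrow(g), 1000)
  X <- as.matrix(as.data.frame(g)[, c("a", "b")])
  expect_lt(max(abs(colMeans(X))), 0.2)
  m <- 0.05 * diff(range(df$y))
  expect_true(all(g$y >= min(df$y) - m & g$y <= max(df$y) + m))
  expect_true(all(attr(g, "bins_assigned") %in% seq_len(bins$n_bins)))
  expect_equal(nrow(vae_generate(st, bins, 0)), 0)
})

test_that("augment_dataset meets quotas, conserves provenance and is deterministic", {
  sp <- default_synth_train(n_total = 160, seed = 31)
  cfg <- sdml_config(augment = list(expansion_factor = 3), vae = list(epochs = 40))
  res <- augment_dataset(sp$train, config = cfg, seed = 7)
  n0 <- nrow(sp$train)
  expect_equal(nrow(res$table), 3 * n0)
  prov <- table(res$table$.provenance)
  expect_equal(unname(prov["original"]), n0)
  expect_equal(sum(prov) - n0, sum(res$bins$quota))
  expect_true(all(c("smote", "vae") %in% names(prov)))

  # stratification: synthetic targets lie in or near their bins
  expect_true(res$report$quota_met)
  # balance improves
  expect_gt(res$report$balance_after, res$report$balance_before)

  res2 <- augment_dataset(sp$train, config = cfg, seed = 7)
  expect_identical(as.data.frame(res$table), as.data.frame(res2$table))

  # expansion 1 is a no-op
  res1 <- augment_dataset(sp$train, config = sdml_config(augment = list(expansion_factor = 1)), seed = 7)
  expect_equal(nrow(res1$table), n0)
  expect_true(all(res1$table$.provenance == "original"))
  expect_equal(as.data.frame(res1$table)[names(as.data.frame(sp$train))],
               as.data.frame(sp$train), ignore_attr = TRUE)
})

test_that("per-bin target means drift within a quarter standard deviation", {
  sp <- default_synth_train(n_total = 616, seed = 51)
  res <- augment_dataset(sp$train,
                         config = sdml_config(augment = list(expansion_factor = 3),
                                              vae = list(epochs = 60)), seed = 3)
  pb <- res$report$per_bin
  occupied <- pb$n_before > 1 & pb$std_before > 0
  expect_true(all(abs(pb$mean_drift[occupied]) <= 0.25 * pb$std_before[occupied]))
})
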