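# shared fixtures, all generated in code

# small deterministic table with a linear truth for model/equation tests
linear_fixture <- function(n = 120, seed = 11, noise = 0.05) {
  withr::with_seed(seed, {
    df <- data.frame(x1 = stats::runif(n, -2, 2),
                     x2 = stats::runif(n, -2, 2),
                     x3 = stats::runif(n, -2, 2))
    df$y <- 3 * df$x1 + df$x2 + stats::rnorm(n, 0, noise)
    feature_table(df, target = "y")
  })
}

# benchmark table for the informative-vs-noise recovery suites
recovery_fixture <- function(seed, n = 150, n_inf = 5, n_noise = 15) {
  withr::with_seed(seed, {
    X <- as.data.frame(matrix(stats::rnorm(n * (n_inf + n_noise)), n))
    names(X) <- c(paste0("inf", seq_len(n_inf)), paste0("nse", seq_len(n_noise)))
    coefs <- c(3, 2.5, 2, 1.5, 1.5)[seq_len(n_inf)]
    X$y <- as.numeric(as.matrix(X[, seq_len(n_inf)]) %*% coefs) + stats::rnorm(n, 0, 0.5)
    feature_table(X, target = "y")
  })
}

default_synth_train <- function(n_total = 200, seed = 101) {
  sim <- simulate_dataset(generator_spec(n = n_total, seed = seed))
  split_train_test(sim$table, 0.75, seed = seed)
}
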