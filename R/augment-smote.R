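#' SMOTER: interpolation-based synthetic samples for regression
#'
#' Generates synthetic rows by interpolating between a seed row and one of its
#' k nearest neighbours within the same target bin:
#' `x_new = x_i + mu * (x_nn - x_i) + delta`, `mu ~ U(0, 1)`, with
#' `delta_f ~ Normal(0, (noise_scale * sd_f)^2)` added independently per
#' continuous feature (proportional to each feature's scale). The target is
#' interpolated with the same `mu` and receives no noise
#' (`y_new = y_i + mu * (y_nn - y_i)`), so every synthetic target lies inside
#' its donor bin. Categorical features are copied from the seed row.
#' Neighbourhoods use the standardized Euclidean metric over continuous
#' features, restricted to rows of the same bin, with a large additive
#' penalty per mismatching categorical code (as in SMOTE variants for mixed
#' data): interpolation partners share the seed row's categorical profile
#' whenever the bin offers one, keeping category-conditional feature-target
#' relationships intact.
#'
#' Samples are allocated over bins proportionally to `bins$quota` (uniformly
#' over eligible bins when all quotas are zero); bins with fewer than 2 donor
#' rows are skipped. Every random draw (seed row, neighbour, `mu`, `delta`)
#' is logged in the `draws` attribute of the result so that generation can be
#' replayed and audited exactly.
#'
#' @param train A preprocessed [feature_table()] with target.
#' @param bins A `bin_partition` over the training target ([make_bins()]).
#' @param k_neighbors Number of in-bin nearest neighbours considered.
#' @param noise_scale Per-feature noise multiplier (0 disables `delta`).
#' @param n Number of synthetic rows to generate.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return A [feature_table()] of `n` synthetic rows with attributes `draws`
#'   (data frame: bin, seed row index, neighbour index, mu) and `delta`
#'   (noise matrix, columns = continuous features).
#' @export
smote_generate <- function(train, bins, k_neighbors = 5, noise_scale = 0.02,
                           n = nrow(train), seed = NULL) {
  if (n < 0) stop("argument error: n must be non-negative", call. = FALSE)
  stopifnot(inherits(bins, "bin_partition"))
  df <- as.data.frame(train)
  tn <- target_name(train)
  cont <- continuous_features(train)
  catf <- categorical_features(train)
  y <- df[[tn]]
  assign_vec <- bin_assign(bins$edges, y)
  donors <- split(seq_len(nrow(df)), factor(assign_vec, levels = seq_len(bins$n_bins)))
  eligible <- which(vapply(donors, length, integer(1)) >= 2)
  if (length(eligible) == 0) stop("no bin has at least 2 donor rows", call. = FALSE)

  if (n == 0) {
    out <- ft_replace(train, df[0, , drop = FALSE])
    attr(out, "draws") <- data.frame(bin = integer(), i = integer(),
                                     nn = integer(), mu = numeric())
    attr(out, "delta") <- matrix(0, 0, length(cont), dimnames = list(NULL, cont))
    return(out)
  }

  sds <- vapply(df[cont], function(v) { s <- stats::sd(v); if (is.finite(s) && s > 0) s else 1 }, numeric(1))
  Xs <- scale(as.matrix(df[, cont, drop = FALSE]), center = TRUE,
              scale = vapply(df[cont], function(v) { s <- stats::sd(v); if (is.finite(s) && s > 0) s else 1 }, numeric(1)))

  # allocate n over eligible bins by quota (largest remainder)
  qv <- bins$quota[eligible]
  wts <- if (sum(qv) > 0) qv / sum(qv) else rep(1 / length(eligible), length(eligible))
  shares <- n * wts
  alloc <- floor(shares)
  remn <- n - sum(alloc)
  if (remn > 0) {
    extra <- order(-(shares - alloc), seq_along(shares))[seq_len(remn)]
    alloc[extra] <- alloc[extra] + 1
  }

  maybe_with_seed(seed, {
    rows <- vector("list", n)
    draws <- data.frame(bin = integer(n), i = integer(n), nn = integer(n), mu = numeric(n))
    delta_log <- matrix(0, n, length(cont), dimnames = list(NULL, cont))
    pos <- 0L
    for (bi in seq_along(eligible)) {
      b <- eligible[bi]
      idx_b <- donors[[b]]
      if (alloc[bi] == 0) next
      # in-bin neighbour lists under the standardized metric, plus a strong
      # penalty per categorical mismatch so partners share the seed's profile
      Db <- as.matrix(stats::dist(Xs[idx_b, , drop = FALSE]))
      for (cf in catf) {
        v <- df[[cf]][idx_b]
        Db <- Db + 1e3 * outer(v, v, "!=")
      }
      diag(Db) <- Inf
      k_eff <- min(k_neighbors, length(idx_b) - 1L)
      nn_order <- apply(Db, 1, function(r) order(r)[seq_len(k_eff)], simplify = FALSE)
      for (s in seq_len(alloc[bi])) {
        pos <- pos + 1L
        ii <- sample.int(length(idx_b), 1)
        nn_local <- nn_order[[ii]][sample.int(k_eff, 1)]
        i_row <- idx_b[ii]
        nn_row <- idx_b[nn_local]
        mu <- stats::runif(1)
        delta <- stats::rnorm(length(cont), 0, noise_scale * sds)
        xi <- as.numeric(df[i_row, cont])
        xnn <- as.numeric(df[nn_row, cont])
        new_row <- df[i_row, , drop = FALSE]
        new_row[cont] <- as.list(xi + mu * (xnn - xi) + delta)
        new_row[[tn]] <- y[i_row] + mu * (y[nn_row] - y[i_row])
        if (length(catf)) new_row[catf] <- df[i_row, catf]
        rows[[pos]] <- new_row
        draws$bin[pos] <- b; draws$i[pos] <- i_row; draws$nn[pos] <- nn_row; draws$mu[pos] <- mu
        delta_log[pos, ] <- delta
      }
    }
    out_df <- do.call(rbind, rows[seq_len(pos)])
    rownames(out_df) <- NULL
    out <- ft_replace(train, out_df)
    attr(out, "draws") <- draws[seq_len(pos), , drop = FALSE]
    attr(out, "delta") <- delta_log[seq_len(pos), , drop = FALSE]
    out
  })
}
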