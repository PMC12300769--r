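#' Construct derived features
#'
#' Appends domain-motivated composites and generic nonlinear expansions to a
#' descriptor table:
#'
#' * `water_solubility_index = TPSA / (MW * (1 + 0.5 * logKow))` — a
#'   solubility proxy combining polarity, size and hydrophobicity; rows where
#'   the denominator is numerically zero get `NA`.
#' * `absorption_kinetics = 1 - exp(-0.005 * ExposureTime)` — first-order
#'   saturating uptake kinetics (0 at t = 0, -> 1 as t grows).
#' * per base feature: square (`sq_f`), `sqrt(|f|)` (`sqrt_abs_f`),
#'   `ln(|f| + eps)` (`ln_abs_f`); pairwise products (`prod_f_g`) over the
#'   configured base features.
#'
#' With the default five base features this appends 27 derived columns.
#' Base-feature names are matched case-sensitively; composites whose
#' ingredients are absent are skipped silently, generic expansions use
#' whichever base features are present.
#'
#' @param x A [feature_table()].
#' @param base_features Features entering the generic expansions.
#' @param eps Floor inside the protected logarithm.
#' @return A [feature_table()] with the derived columns appended (continuous).
#' @export
derive_features <- function(x, base_features = c("MW", "logKow", "pKa", "TPSA", "ExposureTime"),
                            eps = 1e-6) {
  df <- as.data.frame(x)
  if (all(c("TPSA", "MW", "logKow") %in% names(df))) {
    den <- df$MW * (1 + 0.5 * df$logKow)
    wsi <- ifelse(abs(den) < 1e-12, NA_real_, df$TPSA / den)
    df$water_solubility_index <- wsi
  }
  if ("ExposureTime" %in% names(df)) {
    df$absorption_kinetics <- 1 - exp(-0.005 * df$ExposureTime)
  }
  base <- intersect(base_features, names(df))
  for (f in base) {
    df[[paste0("sq_", f)]] <- df[[f]]^2
    df[[paste0("sqrt_abs_", f)]] <- sqrt(abs(df[[f]]))
    df[[paste0("ln_abs_", f)]] <- log(abs(df[[f]]) + eps)
  }
  if (length(base) >= 2) {
    pairs <- utils::combn(base, 2)
    for (p in seq_len(ncol(pairs))) {
      f1 <- pairs[1, p]; f2 <- pairs[2, p]
      df[[paste0("prod_", f1, "_", f2)]] <- df[[f1]] * df[[f2]]
    }
  }
  kinds <- column_kinds(x)
  new_cols <- setdiff(names(df), names(as.data.frame(x)))
  kinds <- c(kinds, stats::setNames(rep("continuous", length(new_cols)), new_cols))
  feature_table(df, target = target_name(x), kinds = kinds)
}

#' Composite multi-statistic feature scoring
#'
#' Ranks features against the target by combining five complementary
#' dependence statistics — the univariate F-statistic (linear), kNN mutual
#' information (nonlinear), distance correlation (general), the maximal
#' information coefficient (grid-based) and RReliefF (local, instance-based).
#' Each statistic is min-max normalized across features and combined with
#' weights summing to one; the combined score is then multiplied by a
#' bootstrap stability factor (the fraction of resamples in which the feature
#' ranks in the top half) and a multicollinearity penalty
#' `1 / (1 + max(0, VIF - vif_cap) / vif_cap)`, keeping the final composite
#' in `[0, 1]`. Duplicated (collinear) features are thereby driven toward 0.
#'
#' @param x A [feature_table()] with target; at least 20 rows.
#' @param n_bootstrap Number of bootstrap resamples for the stability factor.
#' @param weights Named weights over
#'   `c("f_stat","mutual_info","dist_corr","mic","relieff")`; renormalized to
#'   sum 1.
#' @param seed Integer seed (bootstrap resampling).
#' @param vif_cap VIF value above which the penalty engages (default 10).
#' @param bootstrap_fraction Resample size as a fraction of n.
#' @param mi_k,relieff_k Neighbour counts for the MI and ReliefF estimators.
#' @return A `feature_scores` data frame, one row per feature, sorted by
#'   descending composite (ties broken by feature name).
#' @export
score_features <- function(x, n_bootstrap = 100,
                           weights = c(f_stat = 0.2, mutual_info = 0.2,
                                       dist_corr = 0.2, mic = 0.2, relieff = 0.2),
                           seed = 1, vif_cap = 10, bootstrap_fraction = 0.8,
                           mi_k = 3, relieff_k = 10) {
  if (nrow(x) < 20) stop("insufficient data: scoring needs at least 20 rows", call. = FALSE)
  y <- target_values(x)
  feats <- feature_names(x)
  X <- as.matrix(as.data.frame(x)[, feats, drop = FALSE])
  storage.mode(X) <- "double"
  w <- weights[c("f_stat", "mutual_info", "dist_corr", "mic", "relieff")]
  w <- w / sum(w)

  raw <- raw_stat_matrix(X, y, mi_k = mi_k, relieff_k = relieff_k)
  comp_raw <- composite_from_raw(raw, w)

  m <- max(1L, round(bootstrap_fraction * nrow(X)))
  half <- ceiling(length(feats) / 2)
  top_counts <- numeric(length(feats))
  withr::with_seed(seed, {
    for (b in seq_len(n_bootstrap)) {
      idx <- sample.int(nrow(X), m, replace = TRUE)
      rb <- raw_stat_matrix(X[idx, , drop = FALSE], y[idx],
                            mi_k = mi_k, relieff_k = relieff_k)
      cb <- composite_from_raw(rb, w)
      top <- rank(-cb, ties.method = "first") <= half
      top_counts <- top_counts + top
    }
  })
  stability <- if (n_bootstrap > 0) top_counts / n_bootstrap else rep(1, length(feats))

  vif <- vapply(seq_along(feats), function(j) vif_one(X, j), numeric(1))
  constant <- apply(X, 2, stats::sd) == 0
  penalty <- 1 / (1 + pmax(0, vif - vif_cap) / vif_cap)
  penalty[!is.finite(vif)] <- 0
  composite <- comp_raw * stability * penalty
  composite[constant] <- 0

  out <- data.frame(feature = feats,
                    f_stat = raw[, "f_stat"], mutual_info = raw[, "mutual_info"],
                    dist_corr = raw[, "dist_corr"], mic = raw[, "mic"],
                    relieff = raw[, "relieff"],
                    stability = stability, vif = vif,
                    composite = composite, flagged = constant | !is.finite(vif),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$composite, out$feature), ]
  rownames(out) <- NULL
  class(out) <- c("feature_scores", "data.frame")
  out
}

raw_stat_matrix <- function(X, y, mi_k = 3, relieff_k = 10) {
  p <- ncol(X)
  rel <- relieff_weights(X, y, k = relieff_k)
  out <- matrix(0, p, 5, dimnames = list(colnames(X),
    c("f_stat", "mutual_info", "dist_corr", "mic", "relieff")))
  # y-side structures shared across features
  sdy <- stats::sd(y)
  dy <- if (sdy > 0) abs(outer((y - mean(y)) / sdy, (y - mean(y)) / sdy, "-")) else NULL
  By <- if (sdy > 0) dcenter(abs(outer(y, y, "-"))) else NULL
  dvy <- if (sdy > 0) mean(By * By) else 0
  for (j in seq_len(p)) {
    xj <- X[, j]
    out[j, "f_stat"] <- f_statistic(xj, y)
    if (sdy > 0) {
      out[j, "mutual_info"] <- mi_knn_pre(xj, dy, k = mi_k)
      out[j, "dist_corr"] <- dcor_pre(xj, By, dvy)
    }
    out[j, "mic"] <- mic_approx(xj, y)
  }
  out[, "relieff"] <- rel
  out
}

composite_from_raw <- function(raw, w) {
  norm <- apply(raw, 2, function(s) {
    rng <- max(s) - min(s)
    if (!is.finite(rng) || rng == 0) return(rep(0, length(s)))
    (s - min(s)) / rng
  })
  as.numeric(norm %*% w)
}

#' Select the top-k features by composite score
#'
#' @param scores A `feature_scores` table from [score_features()].
#' @param k Number of features to keep (ties broken by name; `score_features`
#'   already orders deterministically).
#' @return Character vector of `k` feature names.
#' @export
select_features <- function(scores, k) {
  if (!is.numeric(k) || k <= 0) stop("argument error: k must be a positive integer", call. = FALSE)
  if (k > nrow(scores)) stop("argument error: k exceeds the number of scored features", call. = FALSE)
  scores$feature[seq_len(k)]
}
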