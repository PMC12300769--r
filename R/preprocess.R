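#' Iterative random-forest imputation
#'
#' Fills missing cells by round-robin regression: each incomplete column is
#' regressed on all other columns with a random forest and its missing entries
#' replaced by the forest's predictions, cycling until the largest absolute
#' change between rounds drops below `tol` (relative to the column's scale)
#' or `max_rounds` is reached. Categorical columns are imputed by
#' classification and snapped back to observed codes.
#'
#' @param x A [feature_table()].
#' @param seed Integer seed (forest fitting is stochastic).
#' @param max_rounds Maximum sweeps over the incomplete columns.
#' @param n_trees Trees per forest.
#' @param tol Convergence tolerance on the maximum absolute change, as a
#'   fraction of each column's standard deviation.
#' @return A list `table` (complete [feature_table()]) and `report`
#'   (a `preprocess_report`).
#' @export
impute_missing <- function(x, seed = 1, max_rounds = 10, n_trees = 100, tol = 1e-3) {
  df <- as.data.frame(x)
  miss <- vapply(df, function(col) sum(is.na(col)), integer(1))
  report <- new_preprocess_report(names(df))
  report$n_imputed <- as.integer(miss)
  if (all(miss == 0)) {
    return(list(table = x, report = report))
  }
  if (any(miss == nrow(df))) {
    stop("unimputable: column(s) entirely missing: ",
         paste(names(df)[miss == nrow(df)], collapse = ", "), call. = FALSE)
  }
  if (!any(miss == 0)) {
    stop("unimputable: no fully observed column to anchor imputation", call. = FALSE)
  }
  kinds <- column_kinds(x)
  incomplete <- names(df)[miss > 0]
  # initialize with column median / modal code
  for (cn in incomplete) {
    col <- df[[cn]]
    fill <- if (identical(kinds[[cn]], "categorical")) {
      as.numeric(names(sort(table(col), decreasing = TRUE))[1])
    } else {
      stats::median(col, na.rm = TRUE)
    }
    df[[cn]][is.na(col)] <- fill
  }
  na_mask <- lapply(stats::setNames(incomplete, incomplete),
                    function(cn) is.na(as.data.frame(x)[[cn]]))
  withr::with_seed(seed, {
    for (round in seq_len(max_rounds)) {
      max_change <- 0
      for (cn in incomplete) {
        idx <- na_mask[[cn]]
        others <- setdiff(names(df), cn)
        dat <- df[, others, drop = FALSE]
        fit <- ranger::ranger(
          y = df[[cn]][!idx], x = dat[!idx, , drop = FALSE],
          num.trees = n_trees, num.threads = 1,
          seed = sample.int(.Machine$integer.max, 1)
        )
        pred <- stats::predict(fit, dat[idx, , drop = FALSE])$predictions
        if (identical(kinds[[cn]], "categorical")) {
          obs <- sort(unique(df[[cn]][!idx]))
          pred <- vapply(pred, function(p) obs[which.min(abs(obs - p))], numeric(1))
        }
        scale <- stats::sd(df[[cn]], na.rm = TRUE)
        if (!is.finite(scale) || scale == 0) scale <- 1
        max_change <- max(max_change, max(abs(pred - df[[cn]][idx])) / scale)
        df[[cn]][idx] <- pred
      }
      if (max_change < tol) break
    }
  })
  sdml_log("impute_missing: %d cells in %d columns", sum(miss), length(incomplete))
  list(table = ft_replace(x, df), report = report)
}

#' Trim target outliers by the 1.5-IQR rule
#'
#' Removes rows whose target lies outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, with quartiles computed by linear
#' interpolation (quantile type 7). Only the target is trimmed; feature
#' outliers are left to the tree models. Re-applying the rule after rows were
#' removed may remove more rows (the quartiles shift), so trimming is done
#' once in the pipeline.
#'
#' @param x A [feature_table()] with a target column.
#' @return A list `table` (trimmed) and `report`.
#' @export
trim_outliers <- function(x) {
  if (nrow(x) < 4) stop("insufficient data: need at least 4 rows to trim", call. = FALSE)
  y <- target_values(x)
  q <- stats::quantile(y, c(0.25, 0.75), type = 7, na.rm = TRUE)
  iqr <- q[2] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[2] + 1.5 * iqr
  keep <- y >= lo & y <= hi
  keep[is.na(keep)] <- TRUE  # missing targets are not trimmed, only imputed
  report <- new_preprocess_report(names(x))
  report$n_trimmed[report$column == target_name(x)] <- sum(!keep)
  sdml_log("trim_outliers: removed %d of %d rows ([%.4g, %.4g])",
           sum(!keep), nrow(x), lo, hi)
  list(table = ft_replace(x, as.data.frame(x)[keep, , drop = FALSE]),
       report = report, bounds = c(lower = unname(lo), upper = unname(hi)))
}

#' Sample skewness (adjusted Fisher-Pearson)
#'
#' @param v Numeric vector; `NA`s are dropped.
#' @return The adjusted Fisher-Pearson skewness `g1 * sqrt(n(n-1))/(n-2)`.
#' @export
skewness <- function(v) {
  v <- v[is.finite(v)]
  n <- length(v)
  if (n < 3) return(0)
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  if (s == 0) return(0)
  g1 <- mean((v - m)^3) / s^3
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Log-transform positively skewed columns
#'
#' Each continuous column whose sample skewness exceeds `skew_threshold` is
#' replaced by `log10(x + shift)` with `shift = max(0, eps - min(x))`, which
#' keeps already-positive columns untouched by the shift. The target is
#' transformed under the same rule when `include_target = TRUE` (RCF-style
#' responses are conventionally log10).
#'
#' @param x A [feature_table()].
#' @param skew_threshold Skewness above which a column is transformed
#'   (default 1).
#' @param eps Positivity floor for the shift.
#' @param include_target Also consider the target column.
#' @return A list `table` and `report`; the report records per-column
#'   skewness before/after, the transform applied, and the shift.
#' @export
transform_skewed <- function(x, skew_threshold = 1, eps = 1e-6, include_target = TRUE) {
  df <- as.data.frame(x)
  cols <- continuous_features(x)
  if (include_target && !is.null(target_name(x))) cols <- c(cols, target_name(x))
  report <- new_preprocess_report(names(df))
  for (cn in cols) {
    v <- df[[cn]]
    sk <- skewness(v)
    i <- report$column == cn
    report$skewness_before[i] <- sk
    if (is.finite(sk) && sk > skew_threshold) {
      shift <- max(0, eps - min(v, na.rm = TRUE))
      df[[cn]] <- log10(v + shift)
      report$transform_applied[i] <- "log10"
      report$shift[i] <- shift
      report$skewness_after[i] <- skewness(df[[cn]])
    } else {
      report$skewness_after[i] <- sk
    }
  }
  sdml_log("transform_skewed: %d column(s) log10-transformed",
           sum(report$transform_applied == "log10"))
  list(table = ft_replace(x, df), report = report)
}

#' Encode categorical labels as integer codes
#'
#' Labels are mapped to 0-based integer codes in order of first appearance;
#' already-numeric categorical columns are left unchanged. The label -> code
#' mapping is returned so it can be inverted.
#'
#' @param x A [feature_table()].
#' @return A list `table` and `mapping` (named list of label vectors, one per
#'   encoded column; code `i` corresponds to `mapping[[col]][i + 1]`).
#' @export
encode_categories <- function(x) {
  df <- as.data.frame(x)
  mapping <- list()
  for (cn in categorical_features(x)) {
    col <- df[[cn]]
    if (is.numeric(col)) next
    labels <- unique(col[!is.na(col)])
    mapping[[cn]] <- labels
    df[[cn]] <- match(col, labels) - 1L
  }
  list(table = ft_replace(x, df), mapping = mapping)
}

#' @rdname encode_categories
#' @param mapping Mapping returned by `encode_categories`.
#' @export
decode_categories <- function(x, mapping) {
  df <- as.data.frame(x)
  for (cn in names(mapping)) {
    df[[cn]] <- mapping[[cn]][df[[cn]] + 1L]
  }
  ft_replace(x, df)
}

#' Full preprocessing pipeline
#'
#' Fixed stage order: impute -> trim -> transform -> encode. Row counts
#' reconcile as `n_out = n_in - n_trimmed`.
#'
#' @param x A [feature_table()] with target.
#' @param config An [sdml_config()].
#' @param seed Seed for the imputer.
#' @return A list `table`, `reports` (per stage) and `mapping`.
#' @export
preprocess <- function(x, config = sdml_config(), seed = 1) {
  pc <- config$preprocess
  sdml_log("preprocess: config %s, %d rows in", config_hash(config), nrow(x))
  imp <- impute_missing(x, seed = seed, max_rounds = pc$impute_max_rounds,
                        n_trees = pc$impute_trees, tol = pc$impute_tol)
  trm <- trim_outliers(imp$table)
  trn <- transform_skewed(trm$table, skew_threshold = pc$skew_threshold,
                          eps = pc$shift_eps)
  enc <- encode_categories(trn$table)
  list(table = enc$table,
       reports = list(impute = imp$report, trim = trm$report, transform = trn$report),
       mapping = enc$mapping)
}

new_preprocess_report <- function(columns) {
  data.frame(column = columns, n_imputed = 0L, n_trimmed = 0L,
             skewness_before = NA_real_, skewness_after = NA_real_,
             transform_applied = "none", shift = 0,
             stringsAsFactors = FALSE)
}
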