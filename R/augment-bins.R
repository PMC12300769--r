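# RNG helper: run code under an explicit seed, or under the current RNG
# stream when seed is NULL (so composite operations stay deterministic under
# a single outer seed).
maybe_with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Adaptive target binning
#'
#' Partitions the observed target range into
#' `n_bins = max(6, min(12, floor(n_train / 12)))` bins. The binning strategy
#' follows the target's shape: equal-frequency bins when
#' `|skewness| > skew_threshold` (so sparse tails still receive bins with a
#' similar number of samples), equal-width bins otherwise (preserving the
#' physical meaning of the intervals). Each bin records its sample count and
#' target mean, standard deviation, min and max.
#'
#' @param target Numeric vector of training targets.
#' @param skew_threshold Absolute skewness above which equal-frequency binning
#'   is used (default 1).
#' @return A `bin_partition`: list with `edges` (length `n_bins + 1`),
#'   `stats` (per-bin data frame), `quota` (zeros until [plan_quotas()]),
#'   `strategy`, `n_train`, `n_bins`.
#' @export
#' @examples
#' b <- make_bins(stats::rnorm(462))
#' b$n_bins  # 12
make_bins <- function(target, skew_threshold = 1) {
  n_train <- length(target)
  if (n_train < 24) {
    stop("insufficient data: adaptive binning needs at least 24 training rows",
         call. = FALSE)
  }
  if (anyNA(target)) stop("target contains missing values; impute first", call. = FALSE)
  n_bins <- max(6L, min(12L, floor(n_train / 12)))
  sk <- skewness(target)
  strategy <- if (abs(sk) > skew_threshold) "equal_frequency" else "equal_width"
  edges <- if (strategy == "equal_frequency") {
    e <- stats::quantile(target, probs = seq(0, 1, length.out = n_bins + 1), type = 7)
    if (anyDuplicated(signif(e, 12))) {
      # heavily tied target: fall back to equal width so bins stay distinct
      strategy <- "equal_width"
      seq(min(target), max(target), length.out = n_bins + 1)
    } else e
  } else {
    seq(min(target), max(target), length.out = n_bins + 1)
  }
  edges <- unname(edges)
  idx <- bin_assign(edges, target)
  stats_df <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    yb <- target[idx == b]
    data.frame(bin = b, n_samples = length(yb),
               mean = if (length(yb)) mean(yb) else NA_real_,
               std = if (length(yb) > 1) stats::sd(yb) else 0,
               min = if (length(yb)) min(yb) else NA_real_,
               max = if (length(yb)) max(yb) else NA_real_)
  }))
  structure(list(edges = edges, stats = stats_df,
                 quota = rep(0L, n_bins), strategy = strategy,
                 n_train = n_train, n_bins = n_bins, skewness = sk),
            class = "bin_partition")
}

# map target values to 1..n_bins; values at or beyond the outer edges go to
# the first/last bin
bin_assign <- function(edges, y) {
  findInterval(y, edges, rightmost.closed = TRUE, all.inside = TRUE)
}

#' Plan per-bin synthetic quotas
#'
#' Distributes the total synthetic budget
#' `T = round((expansion_factor - 1) * n_train)` across bins in proportion to
#' each bin's deficit toward the largest bin
#' (`deficit_b = max(n) - n_b`, weight `deficit_b + 1`), using
#' largest-remainder apportionment so the quotas are integers summing exactly
#' to `T`. Sparse bins therefore receive the largest quotas, which is what
#' rebalances the target distribution.
#'
#' @param bins A `bin_partition` from [make_bins()].
#' @param expansion_factor Final-to-original size ratio (>= 1); the default
#'   workflow uses 9 (the training set grows nine-fold).
#' @return The `bin_partition` with its `quota` field filled.
#' @export
plan_quotas <- function(bins, expansion_factor = 9) {
  stopifnot(inherits(bins, "bin_partition"), expansion_factor >= 1)
  total <- round_half_up((expansion_factor - 1) * bins$n_train)
  n <- bins$stats$n_samples
  weightv <- (max(n) - n) + 1
  shares <- total * weightv / sum(weightv)
  base <- floor(shares)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(-(shares - base), seq_along(shares))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  bins$quota <- as.integer(base)
  bins$expansion_factor <- expansion_factor
  bins
}

#' @export
print.bin_partition <- function(x, ...) {
  cat(sprintf("<bin_partition> %d bins (%s), n_train = %d\n",
              x$n_bins, x$strategy, x$n_train))
  print(cbind(x$stats, quota = x$quota))
  invisible(x)
}
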