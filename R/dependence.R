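# Dependence statistics between a candidate feature and a continuous target.
# All estimators return a single non-negative scalar (ReliefF may be negative
# for irrelevant features, which the min-max normalization in score_features
# handles). Constant inputs yield 0.

#' Univariate regression F-statistic
#'
#' `F = r^2 (n - 2) / (1 - r^2)` for the Pearson correlation `r` between
#' feature and target; measures strength of the linear relationship.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Non-negative scalar; 0 for a constant feature.
#' @export
f_statistic <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  r2 <- stats::cor(x, y)^2
  if (r2 >= 1) return(.Machine$double.xmax)
  r2 * (n - 2) / (1 - r2)
}

#' k-nearest-neighbour mutual information (Kraskov estimator)
#'
#' First Kraskov-Stoegbauer-Grassberger estimator with the max-norm in the
#' joint space; suitable for continuous feature/target pairs. Negative
#' estimates are clamped to 0.
#'
#' @param x,y Numeric vectors.
#' @param k Number of neighbours (default 3).
#' @return Estimated mutual information in nats, >= 0.
#' @export
mutual_info_knn <- function(x, y, k = 3) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(y) < k + 2 || stats::sd(y) == 0) return(0)
  y <- (y - mean(y)) / stats::sd(y)
  mi_knn_pre(x, abs(outer(y, y, "-")), k)
}

# x against a precomputed |y_i - y_j| matrix (y already standardized)
mi_knn_pre <- function(x, dy, k = 3) {
  n <- length(x)
  if (n < k + 2 || stats::sd(x) == 0) return(0)
  x <- (x - mean(x)) / stats::sd(x)
  dx <- abs(outer(x, x, "-"))
  dj <- pmax(dx, dy)
  diag(dj) <- Inf
  eps <- apply(dj, 1, function(row) sort(row, partial = k)[k])
  # ties (duplicate rows) can make eps 0; clamp the self-exclusion at 0
  nx <- pmax(rowSums(dx < eps) - 1L, 0L)
  ny <- pmax(rowSums(dy < eps) - 1L, 0L)
  mi <- digamma(k) + digamma(n) - mean(digamma(nx + 1) + digamma(ny + 1))
  max(0, mi)
}

#' Distance correlation
#'
#' Szekely-Rizzo distance correlation from double-centred pairwise distance
#' matrices; detects general (including nonlinear, non-monotone) dependence.
#'
#' @param x,y Numeric vectors.
#' @return Value in `[0, 1]`; 0 for a constant input.
#' @export
dist_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(y) < 3 || stats::sd(y) == 0) return(0)
  B <- dcenter(abs(outer(y, y, "-")))
  dcor_pre(x, B, mean(B * B))
}

# x against a precomputed double-centred y distance matrix
dcor_pre <- function(x, B, dvy) {
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || dvy <= 0) return(0)
  A <- dcenter(abs(outer(x, x, "-")))
  dcov2 <- mean(A * B)
  dvx <- mean(A * A)
  if (dvx <= 0) return(0)
  sqrt(max(0, dcov2) / sqrt(dvx * dvy))
}

dcenter <- function(d) {
  rm <- rowMeans(d)
  d - outer(rm, rep(1, ncol(d))) - outer(rep(1, nrow(d)), colMeans(d)) + mean(d)
}

#' Maximal information coefficient (equi-partition approximation)
#'
#' Scans grid resolutions `(i, j)` with `i * j <= B`, `B = max(4, n^0.6)`,
#' bins both variables by equal-frequency cuts, and reports the maximum of
#' `I(i, j) / log(min(i, j))` over the scanned grids. This is the standard
#' approximation that restricts the MIC search to equipartitions.
#'
#' @param x,y Numeric vectors.
#' @param exponent Grid-budget exponent (`B = n^exponent`, default 0.6).
#' @return Value in `[0, 1]`.
#' @export
mic_approx <- function(x, y, exponent = 0.6) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 8 || stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  B <- max(4, floor(n^exponent))
  kmax <- floor(B / 2)
  binsx <- lapply(2:kmax, function(k) equifreq_bin(x, k))
  binsy <- lapply(2:kmax, function(k) equifreq_bin(y, k))
  best <- 0
  for (i in 2:kmax) {
    jmax <- floor(B / i)
    if (jmax < 2) break
    bx <- binsx[[i - 1]]
    ni <- max(bx)
    for (j in 2:jmax) {
      by <- binsy[[j - 1]]
      nj <- max(by)
      tab <- matrix(tabulate((bx - 1L) * nj + by, ni * nj), ni, nj, byrow = TRUE)
      mi <- plugin_mi(tab)
      norm <- log(min(ni, nj))
      if (norm > 0) best <- max(best, mi / norm)
    }
  }
  min(1, best)
}

equifreq_bin <- function(v, nb) {
  br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = nb + 1), type = 7))
  if (length(br) < 3) br <- unique(c(min(v), stats::median(v), max(v)))
  cut(v, breaks = br, include.lowest = TRUE, labels = FALSE)
}

plugin_mi <- function(tab) {
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  e <- outer(px, py)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / e[nz]))
}

#' RReliefF relevance for regression
#'
#' Regression ReliefF: for every instance and its `k` nearest neighbours in
#' the (range-normalized) feature space, accumulates the probabilities of the
#' feature differing given the target differs versus not, and returns the
#' contrast. Positive values mark features whose local variation tracks
#' target variation; irrelevant features score near (or below) zero.
#'
#' @param X Numeric matrix (rows = instances).
#' @param y Numeric target.
#' @param k Neighbours per instance (default 10).
#' @return Named vector of relevance weights, one per column of `X`.
#' @export
relieff_weights <- function(X, y, k = 10) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  rng <- apply(X, 2, function(col) {
    r <- diff(range(col, finite = TRUE))
    if (!is.finite(r) || r == 0) 1 else r
  })
  Xn <- sweep(sweep(X, 2, apply(X, 2, min)), 2, rng, "/")
  ry <- diff(range(y)); if (ry == 0) ry <- 1
  yn <- (y - min(y)) / ry
  k <- min(k, n - 1)
  D <- as.matrix(stats::dist(Xn, method = "manhattan"))
  diag(D) <- Inf
  NdY <- 0
  NdF <- numeric(p)
  NdYdF <- numeric(p)
  w <- 1 / k
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[seq_len(k)]
    dy <- abs(yn[i] - yn[nb])
    dF <- abs(sweep(Xn[nb, , drop = FALSE], 2, Xn[i, ], "-"))
    NdY <- NdY + w * sum(dy)
    NdF <- NdF + w * colSums(dF)
    NdYdF <- NdYdF + w * colSums(dF * dy)
  }
  denom_hit <- n - NdY
  out <- NdYdF / max(NdY, 1e-12) - (NdF - NdYdF) / max(denom_hit, 1e-12)
  stats::setNames(out, colnames(X))
}

#' Variance inflation factor
#'
#' `1 / (1 - R^2)` of the feature regressed on all other features; values
#' above ~10 flag strong multicollinearity. A perfectly collinear feature
#' returns `Inf`.
#'
#' @param X Numeric matrix of features.
#' @param j Column index of the feature to assess.
#' @return VIF >= 1 (or `Inf`).
#' @export
vif_one <- function(X, j) {
  X <- as.matrix(X)
  if (ncol(X) < 2) return(1)
  yj <- X[, j]
  if (stats::sd(yj) == 0) return(Inf)
  others <- X[, -j, drop = FALSE]
  keep <- apply(others, 2, stats::sd) > 0
  if (!any(keep)) return(1)
  fit <- stats::lm.fit(cbind(1, others[, keep, drop = FALSE]), yj)
  r2 <- 1 - sum(fit$residuals^2) / sum((yj - mean(yj))^2)
  if (r2 >= 1 - 1e-12) return(Inf)
  max(1, 1 / (1 - r2))
}
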