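#' High-dimensional sparse interaction equation (HSIE)
#'
#' Construct-then-select symbolic regression: build the full term dictionary
#' first — every monomial of the chosen features up to `max_order` (squares,
#' cubes and cross products included) plus, for `max_order >= 2`, the
#' transforms `sqrt(|x|)`, `ln(|x| + eps)` and protected pairwise ratios
#' `x / (|y| + eps)` — then select sparsely with an L1-regularized path
#' (5-fold cross-validated penalty choice on standardized columns), refit
#' the selected support by unpenalized least squares so the reported
#' coefficients are on the natural scale, and prune terms whose contribution
#' is numerically negligible. With `max_order = 1` the dictionary is exactly
#' the raw features, so the result reduces to ordinary least squares.
#'
#' @param train A [feature_table()] with target (>= 40 rows).
#' @param max_order Maximum monomial order (default 3).
#' @param seed Integer seed (cross-validation folds).
#' @param features Features entering the dictionary; defaults to all.
#' @param dict_cap Hard cap on dictionary columns (default 20000).
#' @param lambda_rule `"lambda.1se"` (default, sparser) or `"lambda.min"`.
#' @return An [equation()] with `method = "hsie"` and training `fit_r2`.
#' @export
fit_hsie <- function(train, max_order = 3, seed = 1, features = NULL,
                     dict_cap = 20000, lambda_rule = "lambda.1se") {
  if (nrow(train) < 40) stop("insufficient data: HSIE needs at least 40 rows", call. = FALSE)
  stopifnot(max_order >= 1)
  feats <- if (is.null(features)) feature_names(train) else features
  df <- as.data.frame(train)
  y <- target_values(train)

  # multisets of feature indices (i1 <= i2 <= ... <= i_ord) give all
  # monomials of each order
  multisets <- function(p, ord) {
    out <- list()
    rec <- function(prefix, start) {
      if (length(prefix) == ord) {
        out[[length(out) + 1L]] <<- prefix
        return(invisible(NULL))
      }
      for (i in start:p) rec(c(prefix, i), i)
    }
    rec(integer(0), 1L)
    out
  }
  term_list <- list()
  for (ord in seq_len(max_order)) {
    for (ms in multisets(length(feats), ord)) {
      tab <- table(feats[ms])
      term_list[[length(term_list) + 1L]] <-
        lapply(names(tab), function(f)
          list(feature = f, power = as.numeric(tab[[f]]), transform = "identity"))
    }
  }
  if (max_order >= 2) {
    for (f in feats) {
      term_list[[length(term_list) + 1L]] <- list(list(feature = f, power = 1, transform = "sqrt_abs"))
      term_list[[length(term_list) + 1L]] <- list(list(feature = f, power = 1, transform = "ln_abs"))
    }
    if (length(feats) >= 2) {
      for (f1 in feats) for (f2 in feats) {
        if (f1 == f2) next
        term_list[[length(term_list) + 1L]] <-
          list(list(feature = f1, power = 1, transform = "identity"),
               list(feature = f2, power = 1, transform = "inv_abs"))
      }
    }
  }
  keys <- vapply(term_list, term_key, character(1))
  term_list <- term_list[!duplicated(keys)]
  if (length(term_list) > dict_cap) {
    stop("dictionary overflow: ", length(term_list), " terms exceed the cap of ",
         dict_cap, "; reduce the feature set or max_order", call. = FALSE)
  }
  X <- build_dictionary(df, term_list)
  keep <- apply(X, 2, stats::sd) > 1e-12
  X <- X[, keep, drop = FALSE]
  term_list <- term_list[keep]

  if (stats::sd(y) == 0 || ncol(X) == 0) {
    return(equation(terms = list(), intercept = mean(y), method = "hsie", fit_r2 = NA_real_))
  }

  support <- if (ncol(X) < 2) {
    seq_len(ncol(X))
  } else {
    foldid <- withr::with_seed(seed, sample(rep_len(1:5, length(y))))
    cv <- glmnet::cv.glmnet(X, y, alpha = 1, foldid = foldid, standardize = TRUE)
    beta <- as.numeric(stats::coef(cv, s = lambda_rule))[-1]
    which(beta != 0)
  }
  if (max_order == 1) support <- seq_len(ncol(X))  # reduces to OLS on the features
  if (length(support) == 0) {
    # lasso emptied the model; fall back to the single best-correlated term
    support <- which.max(abs(stats::cor(X, y)))
  }

  refit <- function(sup) {
    fit <- stats::lm.fit(cbind(1, X[, sup, drop = FALSE]), y)
    co <- fit$coefficients
    co[is.na(co)] <- 0
    list(intercept = co[1], beta = co[-1])
  }
  fb <- refit(support)
  # prune numerically negligible terms and refit once
  contrib <- abs(fb$beta) * apply(X[, support, drop = FALSE], 2, stats::sd)
  keep2 <- contrib > 1e-7 * stats::sd(y)
  if (any(keep2) && !all(keep2)) {
    support <- support[keep2]
    fb <- refit(support)
  }
  pred <- as.numeric(X[, support, drop = FALSE] %*% fb$beta) + fb$intercept
  sstot <- sum((y - mean(y))^2)
  r2 <- 1 - sum((y - pred)^2) / sstot
  terms <- lapply(seq_along(support), function(i)
    list(factors = term_list[[support[i]]], coef = unname(fb$beta[i])))
  equation(terms = terms, intercept = unname(fb$intercept),
           method = "hsie", fit_r2 = r2)
}
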