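# shared term-dictionary helpers for the equation-construction engines

term_column <- function(df, factors) {
  v <- rep(1, nrow(df))
  for (fc in factors) {
    v <- v * apply_transform(df[[fc$feature]], fc$transform)^fc$power
  }
  v
}

term_key <- function(factors) {
  paste(sort(vapply(factors, function(fc)
    sprintf("%s|%s|%g", fc$feature, fc$transform, fc$power), character(1))),
    collapse = "&")
}

build_dictionary <- function(df, term_list) {
  X <- vapply(term_list, function(tm) term_column(df, tm), numeric(nrow(df)))
  colnames(X) <- vapply(term_list, term_key, character(1))
  X
}

# elastic-net (or OLS for tiny dictionaries) with deterministic folds;
# returns intercept + coefficient vector aligned to the columns of X
penalized_fit <- function(X, y, alpha = 0.5, lambda_rule = "lambda.min") {
  keep <- apply(X, 2, stats::sd) > 1e-12
  beta <- numeric(ncol(X))
  if (sum(keep) == 0) return(list(intercept = mean(y), beta = beta))
  Xk <- X[, keep, drop = FALSE]
  if (ncol(Xk) < 2) {
    fit <- stats::lm.fit(cbind(1, Xk), y)
    co <- fit$coefficients
    co[is.na(co)] <- 0
    beta[keep] <- co[-1]
    return(list(intercept = co[1], beta = beta))
  }
  foldid <- withr::with_seed(1, sample(rep_len(1:5, length(y))))
  cv <- glmnet::cv.glmnet(Xk, y, alpha = alpha, foldid = foldid,
                          standardize = TRUE)
  co <- as.numeric(stats::coef(cv, s = lambda_rule))
  beta[keep] <- co[-1]
  list(intercept = co[1], beta = beta)
}

#' Multilayer feature-transfer equation construction (MFTEC)
#'
#' Select-then-construct symbolic regression in three stages: (1) keep the
#' top-`m` features by composite score, so later terms are built only from
#' chemically relevant descriptors; (2) construct derived blocks — a linear
#' block (the raw features), an interaction block (pairwise products) and a
#' transform block (`sqrt(|x|)`, `ln(|x| + eps)`, squares, plus
#' `exp(-0.005 x)` for time-like features); (3) fit an elastic-net linear
#' model per block and stack them with a non-negative least-squares
#' meta-combiner over the block predictions. Because each block is linear in
#' its terms, the stack flattens exactly into a single equation whose
#' predictions equal the pipeline's.
#'
#' @param train A [feature_table()] with target.
#' @param scores A `feature_scores` table from [score_features()].
#' @param m Number of stage-1 features (default 8).
#' @param time_features Features given the exponential-decay transform.
#' @return An [equation()] (`method = "mftec"`) with attribute
#'   `pipeline_pred` holding the stacked pipeline's training predictions.
#' @export
fit_mftec <- function(train, scores, m = 8, time_features = "ExposureTime") {
  if (!is.numeric(m) || m <= 0) stop("argument error: m must be positive", call. = FALSE)
  m <- min(m, nrow(scores))
  feats <- intersect(select_features(scores, m), feature_names(train))
  df <- as.data.frame(train)
  y <- target_values(train)

  if (stats::sd(y) == 0) {
    eq <- equation(terms = list(), intercept = mean(y), method = "mftec", fit_r2 = NA_real_)
    attr(eq, "pipeline_pred") <- rep(mean(y), length(y))
    return(eq)
  }

  lin_terms <- lapply(feats, function(f) list(list(feature = f, power = 1, transform = "identity")))
  int_terms <- list()
  if (length(feats) >= 2) {
    pairs <- utils::combn(feats, 2)
    int_terms <- lapply(seq_len(ncol(pairs)), function(i)
      list(list(feature = pairs[1, i], power = 1, transform = "identity"),
           list(feature = pairs[2, i], power = 1, transform = "identity")))
  }
  tr_terms <- c(
    lapply(feats, function(f) list(list(feature = f, power = 1, transform = "sqrt_abs"))),
    lapply(feats, function(f) list(list(feature = f, power = 1, transform = "ln_abs"))),
    lapply(feats, function(f) list(list(feature = f, power = 2, transform = "identity"))),
    lapply(intersect(feats, time_features),
           function(f) list(list(feature = f, power = 1, transform = "exp_decay")))
  )
  blocks <- list(linear = lin_terms, interaction = int_terms, transform = tr_terms)
  blocks <- blocks[vapply(blocks, length, integer(1)) > 0]

  fits <- list(); preds <- list()
  for (bn in names(blocks)) {
    Xb <- build_dictionary(df, blocks[[bn]])
    fb <- penalized_fit(Xb, y, alpha = 0.5)
    fits[[bn]] <- fb
    preds[[bn]] <- as.numeric(Xb %*% fb$beta) + fb$intercept
  }
  P <- do.call(cbind, preds)
  # non-negative meta-combiner on centred block predictions
  Pc <- scale(P, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  w <- tryCatch(pracma::lsqnonneg(Pc, yc)$x, error = function(e) rep(1 / ncol(P), ncol(P)))
  if (all(w == 0)) w <- rep(1 / ncol(P), ncol(P))
  c0 <- mean(y) - sum(w * colMeans(P))
  pipeline_pred <- as.numeric(P %*% w) + c0

  # flatten: coefficient of each dictionary term is the weighted sum of its
  # block coefficients; the stack is affine so this is exact
  coef_map <- new.env(parent = emptyenv())
  term_map <- new.env(parent = emptyenv())
  for (bi in seq_along(blocks)) {
    bn <- names(blocks)[bi]
    for (ti in seq_along(blocks[[bn]])) {
      key <- term_key(blocks[[bn]][[ti]])
      add <- w[bi] * fits[[bn]]$beta[ti]
      coef_map[[key]] <- (if (is.null(coef_map[[key]])) 0 else coef_map[[key]]) + add
      term_map[[key]] <- blocks[[bn]][[ti]]
    }
    c0 <- c0 + w[bi] * fits[[bn]]$intercept
  }
  keys <- ls(coef_map)
  terms <- list()
  for (k in keys) {
    if (abs(coef_map[[k]]) > 0) {
      terms[[length(terms) + 1L]] <- list(factors = term_map[[k]], coef = coef_map[[k]])
    }
  }
  sstot <- sum((y - mean(y))^2)
  r2 <- 1 - sum((y - pipeline_pred)^2) / sstot
  eq <- equation(terms = terms, intercept = c0, method = "mftec", fit_r2 = r2)
  attr(eq, "pipeline_pred") <- pipeline_pred
  eq
}
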