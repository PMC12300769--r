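#' Tiered Shapley-value model explanation
#'
#' Attributes each prediction additively to the features, trying three tiers
#' in order and recording which one succeeded:
#'
#' 1. `native` — the engine's own exact attribution (xgboost's built-in
#'    per-feature prediction contributions).
#' 2. `tree` — exact Shapley values of the cover-weighted conditional-
#'    expectation game played on the extracted tree structures (path-dependent
#'    expectations, as tree explainers compute them). All subsets of the
#'    features actually used by the ensemble are enumerated, so additivity
#'    holds to machine precision and unused features get exactly 0; capped at
#'    14 used features.
#' 3. `kernel` — model-agnostic kernel approximation: a locally weighted
#'    linear model over feature coalitions, with the background distribution
#'    summarized by k-means cluster centres (k = 10) of the training data.
#'
#' @param model An `sdml_model` (or a `tree_structure` for the tree tier).
#' @param data A [feature_table()] (or data frame) of rows to explain.
#' @param tier `"auto"` (default) or one of `"native"`, `"tree"`,
#'   `"kernel"` to force a tier.
#' @param kmeans_k Background clusters for the kernel tier.
#' @param kernel_samples Coalition budget cap for the kernel tier.
#' @return An `sdml_explanation`: `shap_values` (rows x features),
#'   `base_value`, `tier_used`.
#' @export
explain_model <- function(model, data, tier = "auto", kmeans_k = 10,
                          kernel_samples = 2048) {
  tiers <- if (tier == "auto") c("native", "tree", "kernel") else tier
  errors <- list()
  for (t in tiers) {
    res <- tryCatch(
      switch(t,
        native = explain_native(model, data),
        tree = explain_tree(model, data),
        kernel = explain_kernel(model, data, kmeans_k, kernel_samples)),
      error = function(e) e)
    if (!inherits(res, "error")) return(res)
    errors[[t]] <- conditionMessage(res)
  }
  stop("explanation error: all tiers failed — ",
       paste(sprintf("%s: %s", names(errors), unlist(errors)), collapse = "; "),
       call. = FALSE)
}

new_explanation <- function(shap, base, tier) {
  structure(list(shap_values = shap, base_value = base, tier_used = tier),
            class = "sdml_explanation")
}

#' @export
print.sdml_explanation <- function(x, ...) {
  cat(sprintf("<sdml_explanation> %d rows x %d features, tier '%s', base %.4f\n",
              nrow(x$shap_values), ncol(x$shap_values), x$tier_used, x$base_value))
  invisible(x)
}

explain_native <- function(model, data) {
  if (!inherits(model, "sdml_model") || model$model_name == "random_forest") {
    stop("no native attribution for this model")
  }
  if (identical(model$params$booster, "dart")) {
    stop("native contributions unsupported for dart boosters")
  }
  X <- as.matrix(as.data.frame(data)[, model$features, drop = FALSE])
  storage.mode(X) <- "double"
  pc <- stats::predict(model$fit, xgboost::xgb.DMatrix(X), predcontrib = TRUE)
  p <- ncol(pc)
  shap <- pc[, -p, drop = FALSE]
  colnames(shap) <- model$features
  new_explanation(shap, base = mean(pc[, p]), tier = "native")
}

# ---- tree tier ------------------------------------------------------------

# Unified tree structure: list(trees = list of data.frames with columns
# node, feature, split, yes, no, value, cover; rule: x <= split goes to
# `yes` when le = TRUE, x < split when le = FALSE), plus base value.
extract_trees <- function(model) {
  if (inherits(model, "tree_structure")) return(model)
  if (!inherits(model, "sdml_model")) stop("cannot extract trees from this model")
  if (model$model_name == "random_forest") {
    extract_trees_ranger(model)
  } else {
    if (identical(model$params$booster, "dart")) {
      stop("tree extraction unsupported for dart boosters")
    }
    extract_trees_xgb(model)
  }
}

extract_trees_xgb <- function(model) {
  dt <- xgboost::xgb.model.dt.tree(model = model$fit)
  dt <- as.data.frame(dt)
  val_col <- if ("Gain" %in% names(dt)) "Gain" else "Quality"
  id2node <- function(ids) as.integer(sub(".*-", "", ids)) + 1L
  trees <- lapply(split(dt, dt$Tree), function(tr) {
    tr <- tr[order(as.integer(sub(".*-", "", tr$ID))), ]
    leaf <- tr$Feature == "Leaf"
    data.frame(node = id2node(tr$ID),
               feature = ifelse(leaf, NA_character_, tr$Feature),
               split = ifelse(leaf, NA_real_, tr$Split),
               yes = ifelse(leaf, NA_integer_, id2node(tr$Yes)),
               no = ifelse(leaf, NA_integer_, id2node(tr$No)),
               value = ifelse(leaf, tr[[val_col]], NA_real_),
               cover = tr$Cover, stringsAsFactors = FALSE)
  })
  cfg <- xgboost::xgb.config(model$fit)
  if (is.character(cfg)) cfg <- jsonlite::fromJSON(cfg)
  base <- as.numeric(cfg$learner$learner_model_param$base_score)
  structure(list(trees = trees, base = base, le = FALSE,
                 features = model$features),
            class = "tree_structure")
}

extract_trees_ranger <- function(model) {
  fit <- model$fit
  Xtr <- as.data.frame(as.data.frame(model$train)[, model$features, drop = FALSE])
  ntree <- fit$num.trees
  trees <- lapply(seq_len(ntree), function(t) {
    ti <- ranger::treeInfo(fit, t)
    tab <- data.frame(node = ti$nodeID + 1L,
                      feature = ti$splitvarName,
                      split = ti$splitval,
                      yes = ti$leftChild + 1L,
                      no = ti$rightChild + 1L,
                      value = ti$prediction,
                      cover = NA_real_, stringsAsFactors = FALSE)
    tab$cover <- tree_cover(tab, Xtr, le = TRUE)
    tab
  })
  # each ranger tree predicts the response; the forest averages them
  for (t in seq_along(trees)) trees[[t]]$value <- trees[[t]]$value / ntree
  structure(list(trees = trees, base = 0, le = TRUE, features = model$features),
            class = "tree_structure")
}

# number of training rows reaching each node
tree_cover <- function(tab, X, le = TRUE) {
  cover <- numeric(nrow(tab))
  rec <- function(node, idx) {
    cover[node] <<- length(idx)
    if (is.na(tab$feature[node])) return(invisible(NULL))
    v <- X[[tab$feature[node]]][idx]
    go <- if (le) v <= tab$split[node] else v < tab$split[node]
    rec(tab$yes[node], idx[go])
    rec(tab$no[node], idx[!go])
  }
  rec(1L, seq_len(nrow(X)))
  cover
}

# E[tree(x) | x_S] for all rows at once: conditioned splits partition rows,
# marginalized splits weight both children by cover fractions
tree_expv <- function(tab, X, S, le) {
  n <- nrow(X)
  out <- numeric(n)
  rec <- function(node, idx, w) {
    if (is.na(tab$feature[node])) {
      out[idx] <<- out[idx] + w * tab$value[node]
      return(invisible(NULL))
    }
    f <- tab$feature[node]
    if (f %in% S) {
      v <- X[[f]][idx]
      go <- if (le) v <= tab$split[node] else v < tab$split[node]
      if (any(go)) rec(tab$yes[node], idx[go], w)
      if (any(!go)) rec(tab$no[node], idx[!go], w)
    } else {
      cy <- tab$cover[tab$node == tab$yes[node]]
      cn <- tab$cover[tab$node == tab$no[node]]
      tot <- cy + cn
      rec(tab$yes[node], idx, w * cy / tot)
      rec(tab$no[node], idx, w * cn / tot)
    }
  }
  rec(1L, seq_len(n), 1)
  out
}

explain_tree <- function(model, data, max_used = 14) {
  ts <- extract_trees(model)
  df <- as.data.frame(data)
  feats <- ts$features
  used <- sort(unique(stats::na.omit(unlist(lapply(ts$trees, `[[`, "feature")))))
  m <- length(used)
  if (m > max_used) stop("too many used features (", m, ") for exact tree enumeration")
  n <- nrow(df)
  shap <- matrix(0, n, length(feats), dimnames = list(NULL, feats))
  ens_expv <- function(S) {
    v <- numeric(n)
    for (tab in ts$trees) v <- v + tree_expv(tab, df, S, ts$le)
    v + ts$base
  }
  if (m == 0) {
    base <- ens_expv(character(0))[1]
    return(new_explanation(shap, base, "tree"))
  }
  nsub <- bitwShiftL(1L, m)
  V <- matrix(0, n, nsub)
  for (s in 0:(nsub - 1)) {
    V[, s + 1] <- ens_expv(used[bitwAnd(bitwShiftL(1L, seq_len(m) - 1L), s) > 0])
  }
  fact <- factorial(0:m)
  sizes <- vapply(0:(nsub - 1), function(s) sum(bitwAnd(bitwShiftL(1L, seq_len(m) - 1L), s) > 0), numeric(1))
  for (j in seq_len(m)) {
    bit <- bitwShiftL(1L, j - 1L)
    phi <- numeric(n)
    for (s in 0:(nsub - 1)) {
      if (bitwAnd(s, bit) > 0) next
      k <- sizes[s + 1]
      w <- fact[k + 1] * fact[m - k] / fact[m + 1]
      phi <- phi + w * (V[, bitwOr(s, bit) + 1] - V[, s + 1])
    }
    shap[, used[j]] <- phi
  }
  new_explanation(shap, base = mean(V[, 1]), tier = "tree")
}

# ---- kernel tier ----------------------------------------------------------

explain_kernel <- function(model, data, kmeans_k = 10, kernel_samples = 2048) {
  if (!inherits(model, "sdml_model")) stop("kernel tier needs a predictable model")
  feats <- model$features
  df <- as.data.frame(data)[, feats, drop = FALSE]
  Xtr <- as.data.frame(model$train)[, feats, drop = FALSE]
  k <- min(kmeans_k, nrow(unique(Xtr)))
  bg <- if (k < nrow(Xtr)) {
    km <- withr::with_seed(1, stats::kmeans(Xtr, centers = k, nstart = 3, iter.max = 50))
    as.data.frame(km$centers)
  } else Xtr
  colnames(bg) <- feats
  m <- length(feats)
  phi0 <- mean(stats::predict(model, bg))
  Z <- kernel_coalitions(m, kernel_samples)
  w <- kernel_weights(m, rowSums(Z))
  nb <- nrow(bg)
  shap <- matrix(0, nrow(df), m, dimnames = list(NULL, feats))
  for (i in seq_len(nrow(df))) {
    x <- df[i, , drop = FALSE]
    # rows: coalition x background, features from x where z = 1
    big <- bg[rep(seq_len(nb), times = nrow(Z)), , drop = FALSE]
    zrep <- Z[rep(seq_len(nrow(Z)), each = nb), , drop = FALSE]
    for (j in seq_len(m)) big[zrep[, j] == 1, j] <- x[[j]]
    preds <- stats::predict(model, big)
    v <- as.numeric(tapply(preds, rep(seq_len(nrow(Z)), each = nb), mean))
    fx <- stats::predict(model, x)
    delta <- fx - phi0
    yv <- v - phi0
    # substitute the last coefficient to enforce additivity exactly
    y2 <- yv - Z[, m] * delta
    X2 <- Z[, -m, drop = FALSE] - Z[, m]
    WX <- X2 * w
    beta <- tryCatch(solve(crossprod(X2, WX), crossprod(WX, y2)),
                     error = function(e) qr.solve(crossprod(X2, WX) +
                                                    diag(1e-10, ncol(X2)), crossprod(WX, y2)))
    phi <- c(as.numeric(beta), delta - sum(beta))
    shap[i, ] <- phi
  }
  new_explanation(shap, base = phi0, tier = "kernel")
}

kernel_coalitions <- function(m, cap) {
  total <- 2^m - 2
  if (m <= 1) stop("kernel tier needs at least 2 features")
  budget <- min(total, 2 * m + cap)
  if (total <= budget) {
    Z <- t(vapply(1:(2^m - 2), function(s) as.integer(bitwAnd(bitwShiftL(1L, 0:(m - 1)), s) > 0),
                  integer(m)))
  } else {
    sizes <- sample(seq_len(m - 1), budget, replace = TRUE,
                    prob = 1 / (seq_len(m - 1) * (m - seq_len(m - 1))))
    Z <- t(vapply(sizes, function(k) {
      z <- integer(m); z[sample.int(m, k)] <- 1L; z
    }, integer(m)))
    Z <- unique(rbind(Z, diag(1L, m), 1L - diag(1L, m)))
  }
  Z
}

kernel_weights <- function(m, sizes) {
  (m - 1) / (choose(m, sizes) * sizes * (m - sizes))
}

#' Aggregate feature importance across explained models
#'
#' Per model, importance is the mean absolute Shapley value per feature,
#' normalized to sum to 1; the cross-model table is sorted by mean rank.
#'
#' @param explanations Named list of `sdml_explanation` objects (one per
#'   model), all over the same feature set.
#' @return Data frame: one row per feature, per-model importance columns,
#'   `mean_importance`, `mean_rank`; sorted by ascending mean rank.
#' @export
rank_importance <- function(explanations) {
  stopifnot(length(explanations) >= 1)
  featsets <- lapply(explanations, function(e) colnames(e$shap_values))
  if (!all(vapply(featsets, identical, logical(1), y = featsets[[1]]))) {
    stop("alignment error: explanations cover different feature sets", call. = FALSE)
  }
  feats <- featsets[[1]]
  imp <- vapply(explanations, function(e) {
    v <- colMeans(abs(e$shap_values))
    if (sum(v) > 0) v / sum(v) else v
  }, numeric(length(feats)))
  imp <- matrix(imp, nrow = length(feats),
                dimnames = list(feats, names(explanations)))
  rk <- apply(-imp, 2, rank, ties.method = "average")
  out <- data.frame(feature = feats, imp,
                    mean_importance = rowMeans(imp),
                    mean_rank = rowMeans(rk),
                    check.names = FALSE)
  out <- out[order(out$mean_rank, out$feature), ]
  rownames(out) <- NULL
  out
}
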