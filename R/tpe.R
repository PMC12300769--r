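# Tree-structured Parzen estimator (TPE) optimization over mixed,
# conditional hyperparameter spaces.
#
# A space is a list of parameter definitions created by the param_* helpers.
# Continuous parameters are modelled on a linear or log scale; after a random
# start-up phase each trial splits the history into "good" (lowest objective
# quantile) and "bad" sets, fits one-dimensional Parzen (Gaussian kernel)
# densities l(x) and g(x) to each, draws candidates from l and keeps the one
# maximizing l/g. Conditional parameters are sampled only when their
# condition on the partial configuration holds, and their densities use only
# the trials where they were active.

#' Hyperparameter-space constructors
#'
#' Build parameter definitions for [tpe_optimize()]: continuous uniform,
#' continuous log-uniform (for scales spanning orders of magnitude, e.g.
#' learning rates), integer, and categorical parameters. `condition` is an
#' optional function of the partially sampled configuration returning
#' `FALSE` when the parameter is inactive (conditional branches of the
#' space).
#'
#' @param name Parameter name.
#' @param low,high Bounds (inclusive).
#' @param choices Character vector of categorical levels.
#' @param condition `function(params) -> logical`.
#' @return A parameter definition list.
#' @export
param_uniform <- function(name, low, high, condition = NULL) {
  list(name = name, type = "uniform", low = low, high = high, condition = condition)
}

#' @rdname param_uniform
#' @export
param_loguniform <- function(name, low, high, condition = NULL) {
  stopifnot(low > 0)
  list(name = name, type = "loguniform", low = low, high = high, condition = condition)
}

#' @rdname param_uniform
#' @export
param_int <- function(name, low, high, condition = NULL) {
  list(name = name, type = "int", low = low, high = high, condition = condition)
}

#' @rdname param_uniform
#' @export
param_categorical <- function(name, choices, condition = NULL) {
  list(name = name, type = "categorical", choices = choices, condition = condition)
}

p_transform <- function(def, v) if (def$type == "loguniform") log(v) else v
p_backtransform <- function(def, t) {
  v <- if (def$type == "loguniform") exp(t) else t
  v <- min(max(v, def$low), def$high)
  if (def$type == "int") v <- as.integer(round(v)) else v
  v
}

sample_random <- function(def) {
  switch(def$type,
    uniform = stats::runif(1, def$low, def$high),
    loguniform = exp(stats::runif(1, log(def$low), log(def$high))),
    int = sample(seq.int(def$low, def$high), 1),
    categorical = sample(def$choices, 1))
}

sample_tpe_param <- function(def, good_vals, bad_vals, n_candidates) {
  if (def$type == "categorical") {
    lev <- def$choices
    lg <- (tabulate(match(good_vals, lev), length(lev)) + 1)
    bg <- (tabulate(match(bad_vals, lev), length(lev)) + 1)
    score <- (lg / sum(lg)) / (bg / sum(bg))
    pick <- sample(seq_along(lev), 1, prob = lg / sum(lg) * score)
    return(lev[pick])
  }
  tg <- p_transform(def, as.numeric(good_vals))
  tb <- p_transform(def, as.numeric(bad_vals))
  lo <- p_transform(def, def$low); hi <- p_transform(def, def$high)
  span <- hi - lo
  bw_of <- function(v) {
    if (length(v) < 2) return(max(span / 5, 1e-9))
    max(stats::bw.nrd0(v), span / 20, 1e-9)
  }
  bwg <- bw_of(tg); bwb <- bw_of(tb)
  # the "good" model is a mixture of the observation kernels and a uniform
  # prior component over the whole range, which keeps exploration alive
  w_prior <- 1 / (length(tg) + 1)
  dens <- function(x, centers, bw) {
    kde <- if (length(centers)) {
      rowMeans(stats::dnorm(outer(x, centers, "-"), sd = bw))
    } else rep(0, length(x))
    (1 - w_prior) * kde + w_prior / span
  }
  n_unif <- max(1L, round(w_prior * n_candidates))
  cand <- c(stats::runif(n_unif, lo, hi),
            tg[sample.int(length(tg), n_candidates - n_unif, replace = TRUE)] +
              stats::rnorm(n_candidates - n_unif, 0, bwg))
  cand <- pmin(pmax(cand, lo), hi)
  ratio <- dens(cand, tg, bwg) / (dens(cand, tb, bwb) + 1e-300)
  # sample proportionally to the density ratio instead of taking the argmax:
  # a deterministic argmax collapses onto the KDE mode and stalls the search
  pick <- sample.int(length(cand), 1, prob = ratio / sum(ratio))
  p_backtransform(def, cand[pick])
}

#' TPE-guided sequential optimization
#'
#' Minimizes `objective(params)` over a conditional hyperparameter space with
#' a tree-structured Parzen estimator: random exploration for the first
#' `n_startup` trials, then density-ratio guided sampling.
#'
#' @param space List of parameter definitions ([param_uniform()] and kin).
#' @param objective `function(params) -> numeric` to minimize.
#' @param budget Total number of trials (>= 1).
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @param n_startup Random trials before TPE engages.
#' @param gamma Quantile defining the "good" split.
#' @param n_candidates Candidate draws per parameter per trial.
#' @return List: `best_params`, `best_value`, and `history` (one row per
#'   trial with the objective value).
#' @export
tpe_optimize <- function(space, objective, budget, seed = NULL,
                         n_startup = 10, gamma = 0.25, n_candidates = 24) {
  stopifnot(budget >= 1)
  maybe_with_seed(seed, {
    history <- vector("list", budget)
    values <- numeric(budget)
    for (trial in seq_len(budget)) {
      ps <- list()
      for (def in space) {
        active <- is.null(def$condition) || isTRUE(def$condition(ps))
        if (!active) next
        if (trial <= n_startup) {
          ps[[def$name]] <- sample_random(def)
        } else {
          prev <- history[seq_len(trial - 1)]
          act <- !vapply(prev, function(h) is.null(h[[def$name]]), logical(1))
          if (sum(act) < 2) {
            ps[[def$name]] <- sample_random(def)
            next
          }
          vals <- lapply(prev[act], `[[`, def$name)
          obj <- values[seq_len(trial - 1)][act]
          n_good <- max(1L, ceiling(gamma * length(obj)))
          ord <- order(obj)
          good <- unlist(vals[ord[seq_len(n_good)]])
          bad <- unlist(vals[ord[-seq_len(n_good)]])
          if (!length(bad)) bad <- good
          ps[[def$name]] <- sample_tpe_param(def, good, bad, n_candidates)
        }
      }
      values[trial] <- objective(ps)
      history[[trial]] <- ps
    }
    best <- which.min(values)
    list(best_params = history[[best]], best_value = values[best],
         history = data.frame(trial = seq_len(budget), value = values))
  })
}
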