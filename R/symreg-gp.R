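#' Genetic-programming symbolic regression
#'
#' Evolves expression trees over the protected function set
#' `{+, -, *, protected /, protected log, sqrt(|.|), sin, abs, protected
#' power}` with feature and ephemeral-constant terminals. Fitness is
#' `RMSE + parsimony * size`; selection is by tournament, variation by
#' subtree crossover and subtree mutation, with single-elite survival.
#' Default budget is a population of 2000 evolved for 100 generations;
#' reduced budgets return the best individual found so far (`gens = 0`
#' returns the best random individual).
#'
#' @param train A [feature_table()] with target (>= 30 rows).
#' @param pop Population size.
#' @param gens Number of generations.
#' @param seed Integer seed.
#' @param parsimony Size-penalty coefficient (default 0.001).
#' @param tournament Tournament size (default 20).
#' @param p_crossover,p_mutation Variation probabilities (remainder is
#'   reproduction).
#' @param max_depth Depth cap for generated subtrees.
#' @return An [equation()] with `method = "gp"`, the winning expression tree
#'   in `expr`, and `fit_r2` on the training data.
#' @export
fit_gp <- function(train, pop = 2000, gens = 100, seed = 1,
                   parsimony = 0.001, tournament = 20,
                   p_crossover = 0.7, p_mutation = 0.2, max_depth = 8) {
  if (nrow(train) < 30) stop("insufficient data: GP needs at least 30 rows", call. = FALSE)
  df <- as.data.frame(train)
  feats <- feature_names(train)
  y <- target_values(train)

  rand_terminal <- function() {
    if (stats::runif(1) < 0.7) expr_var(sample(feats, 1))
    else expr_const(stats::runif(1, -2, 2))
  }
  rand_tree <- function(depth, full = FALSE) {
    if (depth <= 1 || (!full && stats::runif(1) < 0.3)) return(rand_terminal())
    op <- sample(names(expr_arity), 1)
    args <- replicate(expr_arity[[op]], rand_tree(depth - 1, full), simplify = FALSE)
    c(list(op = op), list(args = args))
  }
  fitness <- function(ind) {
    pred <- tryCatch(rep_len(eval_expr(ind, df), length(y)), error = function(e) NULL)
    if (is.null(pred) || !all(is.finite(pred))) return(Inf)
    sqrt(mean((y - pred)^2)) + parsimony * expr_size(ind)
  }
  # uniformly pick a node address (list of arg indices) in a tree
  pick_node <- function(ind) {
    addrs <- list(integer(0))
    walk <- function(node, addr) {
      if (is.null(node$args)) return(invisible(NULL))
      for (i in seq_along(node$args)) {
        addrs[[length(addrs) + 1L]] <<- c(addr, i)
        walk(node$args[[i]], c(addr, i))
      }
    }
    walk(ind, integer(0))
    addrs[[sample.int(length(addrs), 1)]]
  }
  get_node <- function(ind, addr) {
    for (i in addr) ind <- ind$args[[i]]
    ind
  }
  set_node <- function(ind, addr, sub) {
    if (!length(addr)) return(sub)
    ind$args[[addr[1]]] <- set_node(ind$args[[addr[1]]], addr[-1], sub)
    ind
  }

  withr::with_seed(seed, {
    # ramped half-and-half initialization
    population <- lapply(seq_len(pop), function(i) {
      rand_tree(2 + (i %% 3), full = i %% 2 == 0)
    })
    fit <- vapply(population, fitness, numeric(1))
    select <- function() {
      idx <- sample.int(pop, min(tournament, pop))
      population[[idx[which.min(fit[idx])]]]
    }
    for (g in seq_len(gens)) {
      b0 <- which.min(fit)
      if (fit[b0] - parsimony * expr_size(population[[b0]]) < 1e-12) break  # exact fit
      newpop <- vector("list", pop)
      best <- which.min(fit)
      newpop[[1]] <- population[[best]]
      for (i in 2:pop) {
        r <- stats::runif(1)
        child <- if (r < p_crossover) {
          a <- select(); b <- select()
          cand <- set_node(a, pick_node(a), get_node(b, pick_node(b)))
          if (expr_size(cand) > 2^max_depth) a else cand
        } else if (r < p_crossover + p_mutation) {
          a <- select()
          cand <- set_node(a, pick_node(a), rand_tree(3))
          if (expr_size(cand) > 2^max_depth) a else cand
        } else {
          select()
        }
        newpop[[i]] <- child
      }
      population <- newpop
      fit <- vapply(population, fitness, numeric(1))
    }
    best <- population[[which.min(fit)]]
    pred <- rep_len(eval_expr(best, df), length(y))
    sstot <- sum((y - mean(y))^2)
    r2 <- if (sstot > 0) 1 - sum((y - pred)^2) / sstot else NA_real_
    eq <- equation(method = "gp", fit_r2 = r2, expr = best)
    eq$config <- list(pop = pop, gens = gens, parsimony = parsimony,
                      tournament = tournament)
    eq$train_rmse <- sqrt(mean((y - pred)^2))
    eq
  })
}
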