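#' Symbolic equations: representation, evaluation, serialization
#'
#' An `equation` is a linear combination of terms plus an intercept, where
#' each term is a product of primitive factors `transform(feature)^power`
#' with transform tags `identity`, `sqrt_abs` (`sqrt(|x|)`), `ln_abs`
#' (`log(|x| + eps)`), `exp_decay` (`exp(-0.005 x)`), `kin_decay`
#' (`1 - exp(-0.005 x)`), `inv_abs` (`1 / (|x| + eps)`, the protected
#' reciprocal used by ratio terms), `sin`, and `abs`. Genetic-programming
#' results that are not linear in any dictionary carry a full expression tree
#' in the `expr` field instead of terms. All operators are protected, so
#' evaluation is finite for finite inputs.
#'
#' @param terms List of `list(factors = list(list(feature, power, transform)),
#'   coef = )` entries.
#' @param intercept Intercept.
#' @param method One of `"gp"`, `"mftec"`, `"hsie"` (or `"manual"`).
#' @param fit_r2 Training R^2 recorded at fit time.
#' @param expr Optional expression tree (nested list with `op`/`args`,
#'   `var`, or `const` nodes) used instead of `terms` when present.
#' @return An object of class `equation`.
#' @export
equation <- function(terms = list(), intercept = 0, method = "manual",
                     fit_r2 = NA_real_, expr = NULL) {
  structure(list(terms = terms, intercept = intercept, method = method,
                 fit_r2 = fit_r2, expr = expr),
            class = "equation")
}

eq_term <- function(coef, ...) {
  f <- lapply(list(...), function(fc) {
    list(feature = fc[[1]],
         power = if (length(fc) >= 2) as.numeric(fc[[2]]) else 1,
         transform = if (length(fc) >= 3) fc[[3]] else "identity")
  })
  list(factors = f, coef = coef)
}

apply_transform <- function(v, transform, eps = 1e-6) {
  switch(transform,
    identity = v,
    sqrt_abs = sqrt(abs(v)),
    ln_abs = log(abs(v) + eps),
    exp_decay = exp(-0.005 * v),
    kin_decay = 1 - exp(-0.005 * v),
    inv_abs = 1 / (abs(v) + eps),
    sin = sin(v),
    abs = abs(v),
    stop("unknown transform tag '", transform, "'", call. = FALSE))
}

factor_label <- function(fc) {
  base <- if (fc$transform == "identity") fc$feature else
    sprintf("%s(%s)", fc$transform, fc$feature)
  if (fc$power == 1) base else sprintf("%s^%g", base, fc$power)
}

#' @export
format.equation <- function(x, digits = 4, ...) {
  if (!is.null(x$expr)) {
    return(paste0("y = ", expr_label(x$expr)))
  }
  parts <- vapply(x$terms, function(tm) {
    sprintf("%+.*g*%s", digits, tm$coef,
            paste(vapply(tm$factors, factor_label, character(1)), collapse = "*"))
  }, character(1))
  paste0("y = ", sprintf("%.*g ", digits, x$intercept), paste(parts, collapse = " "))
}

#' @export
print.equation <- function(x, ...) {
  cat(sprintf("<equation> method %s, %d terms, fit R^2 %s\n", x$method,
              length(x$terms),
              if (is.na(x$fit_r2)) "NA" else sprintf("%.4f", x$fit_r2)))
  cat(format(x), "\n")
  invisible(x)
}

#' Evaluate an equation on a table
#'
#' Vectorized evaluation with protected operators. When the table carries a
#' target, the R^2 against it is also returned.
#'
#' @param eq An [equation()].
#' @param data A [feature_table()] or data frame covering the equation's
#'   features.
#' @return List with `predictions` and `r2` (`NA` without a target).
#' @export
evaluate_equation <- function(eq, data) {
  df <- as.data.frame(data)
  feats <- eq_features(eq)
  missing <- setdiff(feats, names(df))
  if (length(missing)) {
    stop("evaluation error: missing feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(df)
  pred <- if (!is.null(eq$expr)) {
    v <- eval_expr(eq$expr, df)
    rep_len(v, n) + eq$intercept
  } else {
    acc <- rep(eq$intercept, n)
    for (tm in eq$terms) {
      v <- rep(1, n)
      for (fc in tm$factors) {
        fv <- apply_transform(df[[fc$feature]], fc$transform)
        v <- v * fv^fc$power
      }
      acc <- acc + tm$coef * v
    }
    acc
  }
  r2 <- NA_real_
  if (inherits(data, "feature_table") && !is.null(target_name(data))) {
    y <- target_values(data)
    sstot <- sum((y - mean(y))^2)
    if (sstot > 0) r2 <- 1 - sum((y - pred)^2) / sstot
  }
  list(predictions = pred, r2 = r2)
}

eq_features <- function(eq) {
  if (!is.null(eq$expr)) return(expr_vars(eq$expr))
  unique(unlist(lapply(eq$terms, function(tm)
    vapply(tm$factors, `[[`, character(1), "feature"))))
}

#' Serialize / parse equations as JSON
#'
#' The JSON round trip preserves the evaluator exactly: parsing a serialized
#' equation yields identical predictions.
#'
#' @param eq An [equation()].
#' @param txt JSON text produced by `eq_serialize`.
#' @return `eq_serialize`: a JSON string; `eq_parse`: an [equation()].
#' @export
eq_serialize <- function(eq) {
  jsonlite::toJSON(unclass(eq), auto_unbox = TRUE, digits = NA,
                   null = "null", na = "null")
}

#' @rdname eq_serialize
#' @export
eq_parse <- function(txt) {
  obj <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  eq <- equation(
    terms = lapply(obj$terms, function(tm) {
      list(factors = lapply(tm$factors, function(fc)
        list(feature = fc$feature, power = as.numeric(fc$power),
             transform = fc$transform)),
        coef = as.numeric(tm$coef))
    }),
    intercept = as.numeric(obj$intercept),
    method = obj$method,
    fit_r2 = if (is.null(obj$fit_r2)) NA_real_ else as.numeric(obj$fit_r2),
    expr = obj$expr
  )
  eq
}

# ---- expression trees (GP) ------------------------------------------------

expr_var <- function(name) list(var = name)
expr_const <- function(value) list(const = value)
expr_call <- function(op, ...) list(op = op, args = list(...))

expr_ops <- list(
  add = function(a, b) a + b,
  sub = function(a, b) a - b,
  mul = function(a, b) a * b,
  div = function(a, b) ifelse(abs(b) > 1e-6, a / b, 1),
  plog = function(a) log(abs(a) + 1e-6),
  psqrt = function(a) sqrt(abs(a)),
  sin = function(a) sin(a),
  abs = function(a) abs(a),
  ppow = function(a, b) {
    e <- pmin(pmax(b, -4), 4)
    out <- exp(pmin(pmax(e * log(abs(a) + 1e-6), -50), 50))
    out
  }
)
expr_arity <- c(add = 2, sub = 2, mul = 2, div = 2, plog = 1, psqrt = 1,
                sin = 1, abs = 1, ppow = 2)

eval_expr <- function(node, df) {
  if (!is.null(node$var)) return(df[[node$var]])
  if (!is.null(node$const)) return(node$const)
  args <- lapply(node$args, eval_expr, df = df)
  do.call(expr_ops[[node$op]], args)
}

expr_vars <- function(node) {
  if (!is.null(node$var)) return(node$var)
  if (!is.null(node$const)) return(character(0))
  unique(unlist(lapply(node$args, expr_vars)))
}

expr_size <- function(node) {
  if (!is.null(node$var) || !is.null(node$const)) return(1L)
  1L + sum(vapply(node$args, expr_size, integer(1)))
}

expr_label <- function(node) {
  if (!is.null(node$var)) return(node$var)
  if (!is.null(node$const)) return(sprintf("%.4g", node$const))
  paste0(node$op, "(", paste(vapply(node$args, expr_label, character(1)),
                             collapse = ", "), ")")
}

#' Example published-style equations
#'
#' Two illustrative log RCF equations in the package's serialization format,
#' written under the convention that exponents bind to the immediately
#' preceding variable and logarithms/divisions are protected. They
#' demonstrate round-trip serialization and protected evaluation; they are
#' illustrations, not fitted or validated models.
#'
#' @return A list of two [equation()] objects.
#' @export
example_equations <- function() {
  eq3 <- equation(
    expr = expr_call("plog",
      expr_call("div", expr_const(0.05),
        expr_call("add",
          expr_call("add", expr_call("ppow", expr_var("logKow"), expr_const(9)),
                    expr_call("ppow", expr_var("pKa"), expr_const(8))),
          expr_var("MW")))),
    method = "manual")
  eq4 <- equation(
    expr = expr_call("add",
      expr_var("MW"),
      expr_call("add",
        expr_call("sin", expr_call("sin", expr_call("add", expr_var("MW"),
          expr_call("add", expr_const(-0.519),
                    expr_call("ppow", expr_var("logKow"), expr_const(6)))))),
        expr_call("plog", expr_call("sub", expr_const(0.05),
          expr_call("sub", expr_call("sin", expr_var("MW")),
                    expr_call("ppow", expr_var("pKa"), expr_const(8))))))),
    method = "manual")
  list(eq3, eq4)
}
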