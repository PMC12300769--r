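#' Construct a feature table
#'
#' A `feature_table` is the universal currency of the workflow: a data frame of
#' chemical-exposure records carrying molecular descriptors (molecular weight,
#' log Kow, pKa, TPSA, ...), exposure covariates (exposure time, plant-species
#' code) and, usually, the response `log RCF` (log10 root concentration
#' factor, dimensionless). Two attributes travel with the data frame: the name
#' of the target column and a feature -> kind map
#' (`"continuous"` or `"categorical"`).
#'
#' Missing values are plain `NA`; categorical columns hold non-negative
#' integer codes once [encode_categories()] has run.
#'
#' @param df A data frame.
#' @param target Name of the target column, or `NULL` for an unlabelled table.
#' @param kinds Named character vector mapping column names to
#'   `"continuous"` or `"categorical"`. Columns not named default to
#'   continuous; the target is never a feature.
#' @return An object of class `feature_table` (inherits `data.frame`).
#' @export
#' @examples
#' ft <- feature_table(data.frame(MW = c(300, 450), logRCF = c(-2, -1)),
#'                     target = "logRCF")
#' feature_names(ft)
feature_table <- function(df, target = NULL, kinds = NULL) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!is.null(target)) {
    if (!target %in% names(df)) {
      stop("schema error: target column '", target, "' not present", call. = FALSE)
    }
  }
  feats <- setdiff(names(df), c(target, ".provenance"))
  k <- stats::setNames(rep("continuous", length(feats)), feats)
  if (!is.null(kinds)) {
    bad <- setdiff(names(kinds), names(df))
    if (length(bad)) stop("schema error: unknown column(s) ", paste(bad, collapse = ", "), call. = FALSE)
    k[intersect(names(kinds), feats)] <- kinds[intersect(names(kinds), feats)]
  }
  if (!all(k %in% c("continuous", "categorical"))) {
    stop("column kinds must be 'continuous' or 'categorical'", call. = FALSE)
  }
  structure(df, target = target, kinds = k,
            class = c("feature_table", "data.frame"))
}

#' @rdname feature_table
#' @param x A `feature_table`.
#' @export
target_name <- function(x) attr(x, "target", exact = TRUE)

#' @rdname feature_table
#' @export
feature_names <- function(x) setdiff(names(x), c(target_name(x), ".provenance"))

#' @rdname feature_table
#' @export
column_kinds <- function(x) attr(x, "kinds", exact = TRUE)

#' @rdname feature_table
#' @export
target_values <- function(x) {
  tn <- target_name(x)
  if (is.null(tn)) stop("table has no target column", call. = FALSE)
  x[[tn]]
}

# continuous feature names only
continuous_features <- function(x) {
  k <- column_kinds(x)
  names(k)[k == "continuous"]
}

categorical_features <- function(x) {
  k <- column_kinds(x)
  names(k)[k == "categorical"]
}

# rebuild a feature_table around a modified data frame, keeping metadata
ft_replace <- function(x, df) {
  feature_table(df, target = target_name(x),
                kinds = column_kinds(x)[intersect(names(column_kinds(x)), names(df))])
}

#' @export
as.data.frame.feature_table <- function(x, ...) {
  df <- x
  attr(df, "target") <- NULL
  attr(df, "kinds") <- NULL
  class(df) <- "data.frame"
  df
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d records, %d features%s\n",
              nrow(x), length(feature_names(x)),
              if (is.null(target_name(x))) "" else paste0(", target '", target_name(x), "'")))
  NextMethod()
}

#' Read a feature table from CSV
#'
#' Reads an RFC-4180 CSV (header row, UTF-8, "." decimal separator). Numeric
#' columns with unparseable cells get `NA` in those cells; rows are never
#' dropped at load time.
#'
#' @param path Path to a CSV file.
#' @param target Name of the target column; `NULL` if the file has none.
#' @param kinds Optional column-kind map as in [feature_table()].
#' @return A [feature_table()].
#' @export
load_table <- function(path, target = NULL, kinds = NULL) {
  if (!file.exists(path)) stop("format error: file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("format error: empty file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0 && ncol(df) == 0) stop("format error: empty file: ", path, call. = FALSE)
  cat_cols <- if (is.null(kinds)) character() else names(kinds)[kinds == "categorical"]
  for (cn in names(df)) {
    col <- df[[cn]]
    if (cn %in% cat_cols) {
      # categorical: keep labels as-is (integer codes load as integers)
      next
    }
    if (is.character(col)) {
      num <- suppressWarnings(as.numeric(ifelse(col %in% c("", "NA", "na", "NaN"), NA, col)))
      df[[cn]] <- num
    }
  }
  ft <- feature_table(df, target = target, kinds = kinds)
  sdml_log("load_table: %d rows, %d columns from %s", nrow(ft), ncol(ft), path)
  ft
}

#' Write a feature table to CSV
#'
#' @param x A [feature_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  sdml_log("write_table: %d rows to %s", nrow(x), path)
  invisible(path)
}

#' Split a table into training and test sets
#'
#' Random permutation split (no stratification). The training size is
#' `round(train_fraction * n)` with half-up rounding so the split is identical
#' across platforms; the same seed always yields the same partition.
#'
#' @param x A [feature_table()].
#' @param train_fraction Proportion of rows assigned to training, in (0, 1).
#' @param seed Integer seed controlling the permutation.
#' @return A list with elements `train` and `test` (both `feature_table`s) and
#'   the index vectors `train_idx`, `test_idx`.
#' @export
#' @examples
#' ft <- make_worked_example()
#' sp <- split_train_test(ft, 0.75, seed = 1)
#' nrow(sp$train); nrow(sp$test)
split_train_test <- function(x, train_fraction = 0.75, seed = 1) {
  n <- nrow(x)
  if (n < 4) stop("insufficient data: need at least 4 rows to split", call. = FALSE)
  stopifnot(train_fraction > 0, train_fraction < 1)
  n_train <- round_half_up(train_fraction * n)
  n_train <- max(1L, min(n - 1L, n_train))
  perm <- withr::with_seed(seed, sample.int(n))
  train_idx <- sort(perm[seq_len(n_train)])
  test_idx <- sort(perm[(n_train + 1L):n])
  sdml_log("split_train_test: %d train / %d test (fraction %.2f, seed %d)",
           n_train, n - n_train, train_fraction, seed)
  list(train = ft_replace(x, x[train_idx, , drop = FALSE]),
       test = ft_replace(x, x[test_idx, , drop = FALSE]),
       train_idx = train_idx, test_idx = test_idx)
}

round_half_up <- function(x) floor(x + 0.5)

# lightweight stage logging, silenced unless option sdml.verbose is TRUE
sdml_log <- function(fmt, ...) {
  if (isTRUE(getOption("sdml.verbose", FALSE))) {
    message(sprintf(paste0("[sdml] ", fmt), ...))
  }
  invisible(NULL)
}
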