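#' Athlete monitoring table
#'
#' A thin data.frame subclass holding numeric indicator columns plus one
#' continuous load-score target column. Missing values are ordinary `NA`s.
#'
#' @param df A data.frame with numeric columns and unique names.
#' @param target Name of the target column (default `"load_score"`).
#' @return A `monitoring_table` (still a data.frame).
#' @export
monitoring_table <- function(df, target = "load_score") {
  df <- as.data.frame(df)
  if (anyDuplicated(names(df)))
    stop("column names must be unique", call. = FALSE)
  if (!target %in% names(df))
    stop("target column '", target, "' not found", call. = FALSE)
  if (ncol(df) < 2L)
    stop("need at least one feature column besides the target", call. = FALSE)
  bad <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric column(s): ", paste(bad, collapse = ", "), call. = FALSE)
  structure(df, target = target,
            class = c("monitoring_table", "data.frame"))
}

#' @export
print.monitoring_table <- function(x, ...) {
  cat(sprintf("<monitoring_table> %d rows, %d features, target '%s'\n",
              nrow(x), ncol(x) - 1L, attr(x, "target")))
  NextMethod()
}

target_column <- function(table) {
  tg <- attr(table, "target")
  if (is.null(tg)) "load_score" else tg
}

feature_names <- function(table) setdiff(names(table), target_column(table))

# Feature matrix X and target matrix Y of a monitoring table.
table_matrices <- function(table) {
  tg <- target_column(table)
  list(X = as.matrix(table[feature_names(table)]),
       Y = matrix(table[[tg]], ncol = 1L, dimnames = list(NULL, tg)))
}

#' Fill missing cells by linear interpolation along row order
#'
#' Monitoring records are time-ordered, so each column's missing cells are
#' filled by linear interpolation between the neighbouring observed values;
#' gaps at either boundary take the nearest observed value. Idempotent on
#' complete tables.
#'
#' @param table A [monitoring_table()]; every column needs at least two
#'   observed values.
#' @return The table with no missing cells.
#' @export
impute_missing <- function(table) {
  stopifnot(inherits(table, "monitoring_table"))
  out <- table
  for (col in names(table)) {
    v <- table[[col]]
    obs <- which(!is.na(v))
    if (length(obs) == length(v)) next
    if (length(obs) < 2L)
      stop("unimputable column '", col, "': fewer than 2 observed values",
           call. = FALSE)
    out[[col]] <- stats::approx(obs, v[obs], xout = seq_along(v),
                                rule = 2)$y
  }
  out
}

#' Min-max normalisation to the unit interval
#'
#' Rescales every column by `(x - min) / (max - min)` using column ranges
#' fitted on `table` (or supplied via `scaler`, e.g. a train-fitted scaler
#' applied to test data, in which case values outside the fitted range map
#' outside \[0, 1\] -- that extrapolation is deliberate and invertible).
#' Constant columns map to 0.
#'
#' @param table A complete (no `NA`) [monitoring_table()].
#' @param scaler Optional `minmax_scaler` from a previous fit.
#' @return A list with `table` (normalised) and `scaler` (class
#'   `minmax_scaler`: per-column `min` and `max`).
#' @export
normalize_table <- function(table, scaler = NULL) {
  stopifnot(inherits(table, "monitoring_table"))
  if (anyNA(table)) stop("table has missing cells; impute first", call. = FALSE)
  if (is.null(scaler)) {
    scaler <- structure(
      list(min = vapply(table, min, numeric(1)),
           max = vapply(table, max, numeric(1))),
      class = "minmax_scaler")
  } else {
    stopifnot(inherits(scaler, "minmax_scaler"))
    if (!setequal(names(scaler$min), names(table)))
      stop("schema error: scaler columns do not match table", call. = FALSE)
  }
  out <- table
  for (col in names(table)) {
    rng <- scaler$max[[col]] - scaler$min[[col]]
    out[[col]] <- if (rng == 0) rep(0, nrow(table))
                  else (table[[col]] - scaler$min[[col]]) / rng
  }
  list(table = out, scaler = scaler)
}

#' Invert min-max normalisation for one column
#'
#' @param values Normalised values.
#' @param scaler A `minmax_scaler`.
#' @param column Column name the values belong to.
#' @return Values on the original scale.
#' @export
denormalize <- function(values, scaler, column) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  if (!column %in% names(scaler$min))
    stop("schema error: no scaler state for column '", column, "'",
         call. = FALSE)
  scaler$min[[column]] + values * (scaler$max[[column]] - scaler$min[[column]])
}

#' Log-transform skewed columns
#'
#' Applies `x -> log(x + offset)` to the selected columns to symmetrise
#' right-skewed indicators.
#'
#' @param table A [monitoring_table()].
#' @param columns Character vector of column names.
#' @param offset Shift added before the log; every `x + offset` must be
#'   positive.
#' @return The transformed table.
#' @export
log_transform <- function(table, columns, offset = 1) {
  stopifnot(inherits(table, "monitoring_table"))
  missing_cols <- setdiff(columns, names(table))
  if (length(missing_cols))
    stop("schema error: unknown column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out <- table
  for (col in columns) {
    v <- table[[col]] + offset
    if (any(v[!is.na(v)] <= 0))
      stop("domain error: non-positive argument to log in column '", col, "'",
           call. = FALSE)
    out[[col]] <- log(v)
  }
  out
}

#' PCA feature selection
#'
#' Projects the (internally centred) feature columns onto the leading
#' principal components of their covariance and keeps the components as the
#' new features. When `n_components` is `NULL`, the smallest number of
#' components explaining at least 95% of the variance is kept.
#'
#' @param table A complete [monitoring_table()].
#' @param n_components Number of components to keep, or `NULL` for the 95%
#'   variance rule.
#' @return A list: `table` (components `PC1..PCk` + target), `loadings`
#'   (feature x component rotation matrix), `explained` (non-increasing
#'   variance fractions of the kept components), `center` (feature means).
#' @export
pca_select <- function(table, n_components = NULL) {
  stopifnot(inherits(table, "monitoring_table"))
  if (anyNA(table)) stop("table has missing cells; impute first", call. = FALSE)
  X <- as.matrix(table[feature_names(table)])
  fit <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  frac <- fit$sdev^2 / sum(fit$sdev^2)
  if (is.null(n_components)) {
    n_components <- which(cumsum(frac) >= 0.95)[1L]
  } else if (n_components > ncol(X)) {
    stop("range error: n_components exceeds feature count", call. = FALSE)
  }
  k <- n_components
  scores <- fit$x[, seq_len(k), drop = FALSE]
  df <- as.data.frame(scores)
  df[[target_column(table)]] <- table[[target_column(table)]]
  list(table = monitoring_table(df, target_column(table)),
       loadings = fit$rotation[, seq_len(k), drop = FALSE],
       explained = frac[seq_len(k)],
       center = fit$center)
}

#' Flag outlying cells by column z-score
#'
#' Reports (does not remove) cells whose column z-score exceeds a threshold;
#' intended as an inspection aid before modelling.
#'
#' @param table A [monitoring_table()].
#' @param threshold Absolute z-score cut-off (default 3).
#' @return Logical matrix of the table's shape; `TRUE` marks a flagged cell.
#' @export
flag_outliers <- function(table, threshold = 3) {
  stopifnot(inherits(table, "monitoring_table"))
  out <- sapply(table, function(v) {
    s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) rep(FALSE, length(v))
    else !is.na(v) & abs((v - mean(v, na.rm = TRUE)) / s) > threshold
  })
  matrix(out, nrow = nrow(table), dimnames = list(NULL, names(table)))
}

#' Seeded train/test split
#'
#' Shuffles rows with the given seed and splits the first `n_train` rows
#' into the training table; the experiment design is 140 training and 14
#' test records out of 154.
#'
#' @param table A [monitoring_table()].
#' @param n_train Training row count, strictly less than the row count.
#' @param seed Integer seed.
#' @return List with `train` and `test` monitoring tables (disjoint,
#'   together exhausting the input rows).
#' @export
split_train_test <- function(table, n_train = 140L, seed = 1L) {
  stopifnot(inherits(table, "monitoring_table"))
  n <- nrow(table)
  if (n_train >= n) stop("size error: n_train must be < row count", call. = FALSE)
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  idx <- perm[seq_len(n_train)]
  tg <- target_column(table)
  list(train = monitoring_table(table[idx, , drop = FALSE], tg),
       test = monitoring_table(table[setdiff(perm, idx), , drop = FALSE], tg))
}
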