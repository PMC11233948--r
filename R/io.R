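#' Read a monitoring table from CSV
#'
#' Expects a header row and numeric cells; empty fields or `NA` mark
#' missing values. Non-numeric cells are reported with their row and
#' column.
#'
#' @param path CSV file path.
#' @param target Target column name (default `"load_score"`).
#' @return A [monitoring_table()].
#' @export
read_table <- function(path, target = "load_score") {
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = c("", "NA"), check.names = FALSE)
  for (col in names(raw)) {
    v <- raw[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad))
      stop("parse error: non-numeric cell at row ", bad[1L], ", column '",
           col, "' in ", path, call. = FALSE)
    raw[[col]] <- num
  }
  monitoring_table(raw, target)
}

#' Write a monitoring table to CSV
#'
#' Missing cells are written as empty fields, so a write/read cycle
#' preserves both values and the missing mask.
#'
#' @param table A [monitoring_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  stopifnot(inherits(table, "monitoring_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

MODEL_FORMAT_VERSION <- 1L

#' Save a trained model and its scaler as JSON
#'
#' Serialises the network parameters, the fitted min-max scaler and run
#' metadata with full double precision, so a reloaded model reproduces
#' forward outputs bit-identically.
#'
#' @param result A `train_result`.
#' @param scaler The `minmax_scaler` fitted on the training data.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
save_model <- function(result, scaler, path) {
  stopifnot(inherits(result, "train_result"),
            inherits(scaler, "minmax_scaler"))
  spec <- result$params$spec
  obj <- list(
    format_version = MODEL_FORMAT_VERSION,
    spec = list(n_input = spec$n_input, n_hidden = spec$n_hidden,
                n_output = spec$n_output),
    theta = flatten_params(result$params),
    scaler = list(columns = names(scaler$min),
                  min = unname(scaler$min), max = unname(scaler$max)),
    best_mse = result$best_mse,
    stop_reason = result$stop_reason,
    seed = result$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path JSON path.
#' @return List with `params` (`mlp_params`), `scaler` (`minmax_scaler`),
#'   `best_mse`, `stop_reason`, `seed`.
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("format error: cannot parse model file: ",
                         conditionMessage(e), call. = FALSE))
  if (is.null(obj$format_version) ||
      obj$format_version != MODEL_FORMAT_VERSION ||
      is.null(obj$spec) || is.null(obj$theta) || is.null(obj$scaler))
    stop("format error: not a recognised model file (version mismatch or ",
         "missing fields)", call. = FALSE)
  spec <- layer_spec(obj$spec$n_input, obj$spec$n_hidden, obj$spec$n_output)
  scaler <- structure(
    list(min = stats::setNames(obj$scaler$min, obj$scaler$columns),
         max = stats::setNames(obj$scaler$max, obj$scaler$columns)),
    class = "minmax_scaler")
  list(params = unflatten_params(obj$theta, spec), scaler = scaler,
       best_mse = obj$best_mse, stop_reason = obj$stop_reason,
       seed = obj$seed)
}
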