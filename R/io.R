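# Delimited-text input/output: survival tables, expression matrices joined
# to clinical data, coefficient files and run metadata.  The separator is
# auto-detected from the file extension (.csv -> comma, otherwise tab).

detect_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a survival table
#'
#' Parses a delimited text file with a header containing columns `time`
#' and `status`; every remaining column must be numeric and becomes a
#' covariate, in file order.  Missing or invalid values are rejected with
#' row/column diagnostics.
#'
#' @param path Path to a `.csv` (comma) or other delimited (tab) file.
#' @param sep Field separator; default auto-detected from the extension.
#' @return A [survival_dataset()].
#' @export
read_survival_table <- function(path, sep = detect_sep(path)) {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  for (col in c("time", "status")) {
    if (!col %in% names(df)) stop(sprintf("missing required column '%s' in %s", col, path))
  }
  covar_cols <- setdiff(names(df), c("time", "status"))
  if (length(covar_cols) == 0L) stop("no covariate columns found")
  for (col in names(df)) {
    vals <- df[[col]]
    if (!is.numeric(vals)) stop(sprintf("column '%s' is not numeric", col))
    if (anyNA(vals)) {
      stop(sprintf("missing value in column '%s', row %d", col, which(is.na(vals))[1]))
    }
  }
  bad <- which(!df$status %in% c(0, 1))
  if (length(bad)) {
    stop(sprintf("invalid status value %g in row %d (must be 0 or 1)",
                 df$status[bad[1]], bad[1]))
  }
  bad_t <- which(df$time <= 0)
  if (length(bad_t)) {
    stop(sprintf("non-positive time %g in row %d", df$time[bad_t[1]], bad_t[1]))
  }
  survival_dataset(df$time, df$status,
                   as.matrix(df[covar_cols]), covar_cols)
}

#' Write a survival table
#'
#' Inverse of [read_survival_table()]: columns `time`, `status`, then the
#' covariates with their feature names.
#'
#' @param data A [survival_dataset()].
#' @param path Output path (`.csv` writes comma-separated, otherwise tab).
#' @return `path`, invisibly.
#' @export
write_survival_table <- function(data, path) {
  df <- data.frame(time = data$time, status = data$status,
                   data$covariates, check.names = FALSE)
  utils::write.table(df, path, sep = detect_sep(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an expression matrix joined to a clinical survival table
#'
#' The expression file holds one row per feature (gene) and one column per
#' sample, with feature identifiers in the first column and sample
#' identifiers in the header.  The clinical file must contain columns
#' `sample`, `time` and `status`.  The matrix is transposed and joined to
#' the clinical table on sample id, preserving the clinical table's sample
#' order; clinical samples absent from the expression matrix are dropped
#' with a warning, and duplicated sample ids are an error.
#'
#' @param path Expression matrix file (features x samples).
#' @param clinical_path Clinical survival table file.
#' @return A [survival_dataset()] whose feature names are the expression
#'   feature identifiers.
#' @export
read_expression_matrix <- function(path, clinical_path) {
  expr <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                            check.names = FALSE, stringsAsFactors = FALSE)
  features <- as.character(expr[[1]])
  mat <- as.matrix(expr[-1])
  if (anyDuplicated(colnames(mat))) {
    stop(sprintf("duplicate sample id '%s' in expression matrix",
                 colnames(mat)[duplicated(colnames(mat))][1]))
  }
  if (anyDuplicated(features)) {
    stop(sprintf("duplicate feature id '%s' in expression matrix",
                 features[duplicated(features)][1]))
  }
  clin <- utils::read.table(clinical_path, header = TRUE,
                            sep = detect_sep(clinical_path),
                            check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("sample", "time", "status")) {
    if (!col %in% names(clin)) {
      stop(sprintf("missing required column '%s' in %s", col, clinical_path))
    }
  }
  clin$sample <- as.character(clin$sample)
  if (anyDuplicated(clin$sample)) {
    stop(sprintf("duplicate sample id '%s' in clinical table",
                 clin$sample[duplicated(clin$sample)][1]))
  }
  matched <- clin$sample %in% colnames(mat)
  if (any(!matched)) {
    warning(sprintf("dropping %d clinical sample(s) absent from the expression matrix: %s",
                    sum(!matched), paste(clin$sample[!matched], collapse = ", ")))
    clin <- clin[matched, , drop = FALSE]
  }
  X <- t(mat[, clin$sample, drop = FALSE])
  storage.mode(X) <- "double"
  survival_dataset(clin$time, clin$status, X, features)
}

#' Write a coefficient file
#'
#' Two-column delimited text (`feature`, `value`), including exact zeros,
#' with full-precision values so that repeated runs are byte-identical and
#' selection metrics are computable downstream without thresholds.
#'
#' @param beta Named (or unnamed) coefficient vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coefficients <- function(beta, path) {
  nm <- names(beta)
  if (is.null(nm)) nm <- paste0("x", seq_along(beta))
  lines <- c("feature\tvalue", sprintf("%s\t%.17g", nm, as.numeric(beta)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a coefficient file written by [write_coefficients()]
#'
#' @param path Input path.
#' @return Named numeric vector.
#' @export
read_coefficients <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df$value), df$feature)
}

#' Write a machine-readable run-metadata record
#'
#' Every pipeline command writes its effective parameters (including
#' seeds) alongside its outputs, as JSON.
#'
#' @param params Named list of parameters.
#' @param path Output path (conventionally `<output>.meta.json`).
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(params, path) {
  params$coxL12_version <- as.character(utils::packageVersion("coxL12"))
  params$timestamp <- format(Sys.time(), tz = "UTC", usetz = TRUE)
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Export a Kaplan-Meier curve as delimited text
#'
#' @param curve A `km_curve` from [km_estimator()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_km_curve <- function(curve, path) {
  df <- data.frame(time = curve$grid_times, survival = curve$survival,
                   at_risk = curve$at_risk, events = curve$events)
  utils::write.table(df, path, sep = detect_sep(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
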