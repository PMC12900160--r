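# Columnar signal cache (Feather) and the canonical CSV tables.

#' Canonical clinical-table column order
#' @return Character vector of required clinical CSV columns.
#' @export
clinical_columns <- function() {
  c("patient_id", "Age", "Gender", "BMI", "AHI", "HeartRate",
    "hypertension", "diabetes", "asthma_copd")
}

#' Canonical feature-matrix column order
#'
#' The eleven per-patient model features: five clinical variables followed by
#' the six engineered event statistics.
#' @param with_id Prepend `patient_id`?
#' @return Character vector of column names.
#' @export
feature_columns <- function(with_id = FALSE) {
  cols <- c("Age", "Gender", "BMI", "AHI", "HeartRate",
            "t3_t1_mean", "t4_t2_mean", "delta_t_FP0_mean",
            "delta_t_SpO2_mean", "mean_delta_SpO2", "mean_slope")
  if (with_id) c("patient_id", cols) else cols
}

#' Cache a trace to a Feather file
#'
#' Lossless columnar storage of one channel (samples as a double column,
#' trace metadata as data-frame attributes, which Feather round-trips).
#'
#' @param trace A [psg_trace()].
#' @param path Output `.feather` path.
#' @return `path`, invisibly.
#' @export
cache_columnar <- function(trace, path) {
  stopifnot_trace(trace)
  df <- data.frame(sample = trace$samples)
  attr(df, "patient_id") <- trace$patient_id
  attr(df, "channel") <- trace$channel
  attr(df, "rate") <- trace$rate
  attr(df, "start_offset") <- trace$start_offset
  arrow::write_feather(df, path)
  invisible(path)
}

#' Load a trace from a Feather cache
#' @param path A `.feather` file written by [cache_columnar()].
#' @return A [psg_trace()].
#' @export
load_columnar <- function(path) {
  if (!file.exists(path)) stop("cache file not found: ", path)
  df <- tryCatch(as.data.frame(arrow::read_feather(path)),
                 error = function(e) stop("corrupt columnar cache ", path, ": ",
                                          conditionMessage(e)))
  need <- c("patient_id", "channel", "rate", "start_offset")
  if (!all(need %in% names(attributes(df))) || !identical(names(df), "sample"))
    stop("corrupt columnar cache ", path, ": missing trace metadata")
  psg_trace(attr(df, "patient_id"), attr(df, "channel"), attr(df, "rate"),
            df$sample, attr(df, "start_offset"))
}

check_schema <- function(found, expected, what) {
  missing <- setdiff(expected, found)
  extra <- setdiff(found, expected)
  if (length(missing) || length(extra))
    stop(what, " schema mismatch; missing: [",
         paste(missing, collapse = ", "), "]; unexpected: [",
         paste(extra, collapse = ", "), "]")
  invisible(TRUE)
}

#' Read a clinical/label table
#'
#' @param path CSV path with columns [clinical_columns()] (labels optional).
#' @param require_labels Require the three comorbidity label columns?
#' @return `data.frame` in canonical column order.
#' @export
read_clinical <- function(path, require_labels = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  cols <- clinical_columns()
  if (!require_labels && !all(c("hypertension", "diabetes", "asthma_copd") %in% names(df)))
    cols <- cols[1:6]
  check_schema(names(df), cols, "clinical table")
  df <- df[, cols, drop = FALSE]
  if (nrow(df)) {
    if (anyDuplicated(df$patient_id)) stop("duplicate patient_id in ", path)
    if (!all(df$Gender %in% c(0, 1))) stop("Gender must be coded 0/1 in ", path)
  }
  df
}

#' Write a clinical/label table
#' @param df Clinical table (canonical columns, any order).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(df, path) {
  cols <- clinical_columns()
  if (!all(c("hypertension", "diabetes", "asthma_copd") %in% names(df)))
    cols <- cols[1:6]
  check_schema(names(df), cols, "clinical table")
  utils::write.csv(df[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Write the per-patient feature matrix
#'
#' Columns are re-emitted in the canonical order regardless of input order.
#'
#' @param df Feature matrix with `patient_id` plus the eleven feature columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(df, path) {
  check_schema(names(df), feature_columns(with_id = TRUE), "feature matrix")
  utils::write.csv(df[, feature_columns(with_id = TRUE), drop = FALSE], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a per-patient feature matrix
#' @param path CSV written by [write_feature_matrix()].
#' @return `data.frame` in canonical column order.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  check_schema(names(df), feature_columns(with_id = TRUE), "feature matrix")
  df[, feature_columns(with_id = TRUE), drop = FALSE]
}
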