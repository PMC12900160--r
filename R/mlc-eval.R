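# Multi-label classification evaluation: per-label confusion metrics,
# macro/micro/weighted aggregation, example-based accuracies, threshold-free
# AUCs, and the fractional multi-label confusion matrix (MLCM) with its
# column-normalized precision and row-normalized recall matrices.

mlc_check <- function(truth, pred = NULL, scores = NULL) {
  truth <- as.matrix(truth)
  if (!all(truth %in% c(0, 1))) stop("truth must be binary")
  if (!is.null(pred)) {
    pred <- as.matrix(pred)
    if (!identical(dim(truth), dim(pred))) stop("truth/pred dimension mismatch")
    if (!all(pred %in% c(0, 1))) stop("predictions must be binary")
  }
  if (!is.null(scores)) {
    scores <- as.matrix(scores)
    if (!identical(dim(truth), dim(scores)))
      stop("truth/scores dimension mismatch")
  }
  invisible(TRUE)
}

#' Per-label confusion counts
#'
#' @param truth,pred N x q binary matrices (rows = samples, columns =
#'   labels).
#' @return Data frame with one row per label: `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(truth, pred) {
  mlc_check(truth, pred)
  truth <- as.matrix(truth); pred <- as.matrix(pred)
  data.frame(
    label = colnames(truth) %||% paste0("label", seq_len(ncol(truth))),
    TP = colSums(truth == 1 & pred == 1),
    FP = colSums(truth == 0 & pred == 1),
    TN = colSums(truth == 0 & pred == 0),
    FN = colSums(truth == 1 & pred == 0),
    row.names = NULL
  )
}

# Zero-denominator convention: a ratio whose denominator is zero is 1 when
# the situation is vacuous (nothing to find, nothing claimed), else 0.
safe_ratio <- function(num, den, vacuous) ifelse(den > 0, num / den,
                                                 ifelse(vacuous, 1, 0))

#' Per-label binary metrics
#'
#' Accuracy `(TP+TN)/N`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and
#' `F1 = 2TP/(2TP+FP+FN)`. A metric with a zero denominator is 1 in the
#' vacuous case (no positives exist and none were predicted) and 0
#' otherwise.
#'
#' @param counts Data frame from [confusion_counts()].
#' @return `counts` extended with `accuracy`, `precision`, `recall`, `F1`.
#' @export
binary_metrics <- function(counts) {
  n <- counts$TP + counts$FP + counts$TN + counts$FN
  vac <- counts$TP + counts$FP + counts$FN == 0
  counts$accuracy <- (counts$TP + counts$TN) / n
  counts$precision <- safe_ratio(counts$TP, counts$TP + counts$FP, vac)
  counts$recall <- safe_ratio(counts$TP, counts$TP + counts$FN, vac)
  counts$F1 <- safe_ratio(2 * counts$TP, 2 * counts$TP + counts$FP + counts$FN,
                          vac)
  counts
}

#' Aggregate a per-label metric across labels
#'
#' `macro`: unweighted mean of the per-label metric. `micro`: the metric
#' recomputed on counts summed over labels. `weighted`: mean weighted by
#' label support (`TP + FN`).
#'
#' @param counts Data frame from [confusion_counts()].
#' @param metric One of `"accuracy"`, `"precision"`, `"recall"`, `"F1"`.
#' @param mode `"macro"`, `"micro"` or `"weighted"`.
#' @return Scalar aggregate.
#' @export
aggregate_metric <- function(counts, metric = "F1",
                             mode = c("macro", "micro", "weighted")) {
  mode <- match.arg(mode)
  metric <- match.arg(metric, c("accuracy", "precision", "recall", "F1"))
  per <- binary_metrics(counts)[[metric]]
  switch(mode,
    macro = mean(per),
    micro = binary_metrics(data.frame(
      TP = sum(counts$TP), FP = sum(counts$FP),
      TN = sum(counts$TN), FN = sum(counts$FN)
    ))[[metric]],
    weighted = {
      support <- counts$TP + counts$FN
      if (sum(support) == 0) mean(per)
      else sum(per * support) / sum(support)
    }
  )
}

#' Example-based multi-label accuracies
#'
#' Subset accuracy (exact label-set match per sample), flat accuracy
#' (bit-level), partial accuracy (mean per-sample Jaccard overlap, with an
#' empty-vs-empty sample counting as 1) and Hamming loss (the exact
#' complement of flat accuracy).
#'
#' @param truth,pred N x q binary matrices.
#' @return List with `subset_accuracy`, `flat_accuracy`, `partial_accuracy`,
#'   `hamming_loss`.
#' @export
example_metrics <- function(truth, pred) {
  mlc_check(truth, pred)
  truth <- as.matrix(truth); pred <- as.matrix(pred)
  eq <- truth == pred
  inter <- rowSums(truth == 1 & pred == 1)
  uni <- rowSums(truth == 1 | pred == 1)
  jacc <- ifelse(uni > 0, inter / uni, 1)
  flat <- mean(eq)
  list(
    subset_accuracy = mean(rowSums(!eq) == 0),
    flat_accuracy = flat,
    partial_accuracy = mean(jacc),
    hamming_loss = 1 - flat
  )
}

# Trapezoidal ROC AUC == Mann-Whitney statistic with half credit for ties.
roc_auc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Step-wise average precision: sum over recall increments of the precision
# at each positive, in decreasing-score order.
average_precision <- function(scores, truth) {
  if (!any(truth == 1) || !any(truth == 0)) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  y <- truth[o]
  prec <- cumsum(y) / seq_along(y)
  sum(prec[y == 1]) / sum(y)
}

#' Macro-averaged threshold-free metrics
#'
#' One-vs-rest per label: trapezoidal ROC area and step-wise average
#' precision, macro-averaged. Labels with a single class in the truth are
#' skipped with a warning; all labels single-class is an error.
#'
#' @param scores N x q matrix of probabilities.
#' @param truth N x q binary matrix.
#' @return List with `auc_roc_macro`, `auc_pr_macro`, `per_label` (data
#'   frame) and `skipped` (labels excluded).
#' @export
auc_metrics <- function(scores, truth) {
  mlc_check(truth, scores = scores)
  scores <- as.matrix(scores); truth <- as.matrix(truth)
  q <- ncol(truth)
  lab <- colnames(truth) %||% paste0("label", seq_len(q))
  roc <- vapply(seq_len(q), function(j) roc_auc(scores[, j], truth[, j]), 0)
  ap <- vapply(seq_len(q), function(j) average_precision(scores[, j], truth[, j]), 0)
  skipped <- lab[is.na(roc)]
  if (length(skipped) == q)
    stop("every label is single-class; AUC undefined")
  if (length(skipped))
    warning("single-class label(s) skipped in AUC aggregation: ",
            paste(skipped, collapse = ", "))
  list(
    auc_roc_macro = mean(roc, na.rm = TRUE),
    auc_pr_macro = mean(ap, na.rm = TRUE),
    per_label = data.frame(label = lab, auc_roc = roc, auc_pr = ap),
    skipped = skipped
  )
}

#' Build the fractional multi-label confusion matrix
#'
#' Row = true label, column = predicted label. For each sample, every
#' correctly predicted true label adds 1 to its diagonal cell. Every missed
#' true label (present in the truth, absent from the prediction) distributes
#' one unit of weight equally across the sample's false-positive labels
#' (predicted but not true), producing the fractional off-diagonal entries.
#' When a sample has no false positives, the missed unit cannot be allocated
#' and is accumulated in the per-label `unallocated` tally instead, so the
#' total true support is always conserved:
#' `rowSums(raw) + unallocated = per-label support`.
#'
#' @param truth,pred N x q binary matrices.
#' @return An `mlcm` object: list with `raw` (q x q), `precision_matrix`
#'   (column-normalized), `recall_matrix` (row-normalized), `precision`
#'   (diagonal of the precision matrix), `recall` (diagonal of the recall
#'   matrix) and `unallocated` (length-q vector).
#' @export
build_mlcm <- function(truth, pred) {
  mlc_check(truth, pred)
  truth <- as.matrix(truth); pred <- as.matrix(pred)
  q <- ncol(truth)
  if (q < 2) stop("MLCM needs at least 2 labels")
  lab <- colnames(truth) %||% paste0("label", seq_len(q))
  raw <- matrix(0, q, q, dimnames = list(lab, lab))
  unalloc <- stats::setNames(numeric(q), lab)
  for (i in seq_len(nrow(truth))) {
    y <- truth[i, ]; z <- pred[i, ]
    hit <- which(y == 1 & z == 1)
    raw[cbind(hit, hit)] <- raw[cbind(hit, hit)] + 1
    missed <- which(y == 1 & z == 0)
    fp <- which(y == 0 & z == 1)
    if (length(missed)) {
      if (length(fp)) {
        for (m in missed) raw[m, fp] <- raw[m, fp] + 1 / length(fp)
      } else {
        unalloc[missed] <- unalloc[missed] + 1
      }
    }
  }
  col_sum <- colSums(raw)
  row_sum <- rowSums(raw)
  prec_m <- sweep(raw, 2, ifelse(col_sum > 0, col_sum, 1), "/")
  rec_m <- sweep(raw, 1, ifelse(row_sum > 0, row_sum, 1), "/")
  structure(list(
    raw = raw,
    precision_matrix = prec_m,
    recall_matrix = rec_m,
    precision = diag(prec_m),
    recall = diag(rec_m),
    unallocated = unalloc
  ), class = "mlcm")
}

#' @export
print.mlcm <- function(x, digits = 2, ...) {
  cat("Raw multi-label confusion matrix (rows = truth, cols = predicted):\n")
  print(round(x$raw, digits))
  cat("Class-wise precision:", paste(round(x$precision, digits),
                                     collapse = " "), "\n")
  cat("Class-wise recall:   ", paste(round(x$recall, digits),
                                     collapse = " "), "\n")
  if (any(x$unallocated > 0))
    cat("Unallocated missed-label mass:",
        paste(round(x$unallocated, digits), collapse = " "), "\n")
  invisible(x)
}

#' Normalize a raw MLCM into precision/recall matrices
#'
#' Column-normalizes (precision) and row-normalizes (recall) an existing raw
#' multi-label confusion matrix, e.g. one quoted from a report.
#'
#' @param raw q x q non-negative matrix (rows = truth, cols = predicted).
#' @return List with `precision_matrix`, `recall_matrix`, `precision`,
#'   `recall`.
#' @export
mlcm_normalize <- function(raw) {
  raw <- as.matrix(raw)
  stopifnot(nrow(raw) == ncol(raw), all(raw >= 0))
  col_sum <- colSums(raw)
  row_sum <- rowSums(raw)
  prec_m <- sweep(raw, 2, ifelse(col_sum > 0, col_sum, 1), "/")
  rec_m <- sweep(raw, 1, ifelse(row_sum > 0, row_sum, 1), "/")
  list(precision_matrix = prec_m, recall_matrix = rec_m,
       precision = diag(prec_m), recall = diag(rec_m))
}

#' Full multi-label metrics report
#'
#' @param truth,pred N x q binary matrices.
#' @param scores Optional N x q probability matrix for the AUC metrics.
#' @return List with the example-based accuracies, Hamming loss, F1
#'   macro/micro/weighted, optional macro AUCs, per-label metrics and the
#'   MLCM.
#' @export
metrics_report <- function(truth, pred, scores = NULL) {
  counts <- confusion_counts(truth, pred)
  ex <- example_metrics(truth, pred)
  rep <- c(ex, list(
    f1_macro = aggregate_metric(counts, "F1", "macro"),
    f1_micro = aggregate_metric(counts, "F1", "micro"),
    f1_weighted = aggregate_metric(counts, "F1", "weighted"),
    per_label = binary_metrics(counts),
    mlcm = build_mlcm(truth, pred)
  ))
  if (!is.null(scores)) {
    a <- tryCatch(auc_metrics(scores, truth), error = function(e) {
      warning("AUC metrics unavailable: ", conditionMessage(e))
      NULL
    })
    rep$auc_roc_macro <- if (is.null(a)) NA_real_ else a$auc_roc_macro
    rep$auc_pr_macro <- if (is.null(a)) NA_real_ else a$auc_pr_macro
  }
  rep
}

#' Demographic stratified error counts
#'
#' Per subgroup and label: TP/FN among label-present patients and TN/FP
#' among label-absent patients, the decomposition used for demographic
#' robustness reporting.
#'
#' @param truth,pred N x q binary matrices (rows aligned with `clinical`).
#' @param clinical Data frame with the stratification variable.
#' @param by Column of `clinical` to stratify on.
#' @param breaks Numeric bin edges for a continuous variable (ignored for
#'   categorical ones).
#' @return Data frame: `stratum`, `label`, `n`, `TP`, `FN`, `TN`, `FP`.
#' @export
stratified_eval <- function(truth, pred, clinical, by = "Age",
                            breaks = NULL) {
  mlc_check(truth, pred)
  truth <- as.matrix(truth); pred <- as.matrix(pred)
  stopifnot(nrow(clinical) == nrow(truth))
  v <- clinical[[by]]
  strat <- if (!is.null(breaks)) {
    cut(v, breaks = breaks, right = FALSE, include.lowest = TRUE)
  } else factor(v)
  lab <- colnames(truth) %||% paste0("label", seq_len(ncol(truth)))
  rows <- list()
  for (s in levels(strat)) {
    idx <- which(strat == s)
    for (j in seq_along(lab)) {
      y <- truth[idx, j]; z <- pred[idx, j]
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, label = lab[j], n = length(idx),
        TP = sum(y == 1 & z == 1), FN = sum(y == 1 & z == 0),
        TN = sum(y == 0 & z == 0), FP = sum(y == 0 & z == 1)
      )
    }
  }
  do.call(rbind, rows)
}

#' Default demographic stratification bins
#'
#' Age in decades 40-70 with open ends; BMI at standard
#' normal/overweight/obesity class edges; gender on its 0/1 coding.
#' @return List of numeric break vectors for `Age` and `BMI`.
#' @export
demographic_bins <- function() {
  list(Age = c(-Inf, 40, 50, 60, 70, Inf),
       BMI = c(-Inf, 25, 30, 35, 40, Inf))
}

#' Bundled truth/prediction fixture regenerating the reference MLCM
#'
#' A 21-sample, 3-label set of ground-truth and predicted label vectors
#' whose fractional MLCM (equal-split allocation of missed labels across a
#' sample's false positives) equals the reference raw matrix used in the
#' worked examples, including its fractional 0.5/2.5 entries.
#'
#' @return List with matrices `truth` and `pred`.
#' @export
mlcm_example_labels <- function() {
  df <- utils::read.csv(system.file("extdata", "mlcm_example_labels.csv",
                                    package = "psgcomorb"))
  list(truth = as.matrix(df[, c("y1", "y2", "y3")]),
       pred = as.matrix(df[, c("z1", "z2", "z3")]))
}

#' Reference raw MLCM from the worked example
#' @return 3 x 3 matrix (rows = truth, cols = predicted).
#' @export
mlcm_reference_raw <- function() {
  matrix(c(4, 0, 4,
           0, 3, 0,
           0.5, 2.5, 7),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("hypertension", "diabetes", "asthma_copd"),
                         c("hypertension", "diabetes", "asthma_copd")))
}
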