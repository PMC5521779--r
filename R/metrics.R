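# Confusion-matrix metrics, ROC/AUC and the NG-motif sequence baseline,
# with the degenerate-case conventions needed for heavily unbalanced
# deamidation data: precision is undefined (not 0) when nothing is
# predicted positive, and MCC is 0 when any denominator factor vanishes,
# so an all-negative predictor scores like a random one.

#' Confusion matrix from binary labels
#'
#' @param truth,predicted Equal-length binary vectors (1/TRUE =
#'   deamidated).
#' @return Object of class `confusion` with integer counts tp, fp, tn, fn.
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length")
  }
  t1 <- as.logical(truth)
  p1 <- as.logical(predicted)
  confusion_counts(tp = sum(t1 & p1), fp = sum(!t1 & p1),
                   tn = sum(!t1 & !p1), fn = sum(t1 & !p1))
}

#' Build a confusion matrix from counts
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return Object of class `confusion`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  stopifnot(all(counts >= 0))
  structure(as.list(counts), class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  cat(sprintf("<confusion> TP %d  FP %d  TN %d  FN %d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Metric suite for a confusion matrix
#'
#' Accuracy, recall (true positive rate), false positive rate,
#' specificity, precision and the Matthews correlation coefficient.
#' Precision is `NA` (printed "-") when tp + fp = 0; MCC is 0 when any
#' factor of its denominator is 0. Values are kept at full precision;
#' use [format_metrics()] for the 2-decimal display convention.
#'
#' @param cm A `confusion` object.
#' @param auc Optional AUC value to carry along in the report.
#' @return A `metrics_report` list.
#' @export
metrics <- function(cm, auc = NULL) {
  stopifnot(inherits(cm, "confusion"))
  tp <- cm$tp; fp <- cm$fp; tn <- cm$tn; fn <- cm$fn
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty confusion matrix")
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = (tp + tn) / total,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
    specificity = if (fp + tn > 0) tn / (fp + tn) else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    mcc = if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else 0,
    auc = auc
  ), class = "metrics_report")
}

# Half-up rounding to match the printed-table convention (R's round()
# rounds half to even).
round_half_up <- function(x, digits = 2) {
  floor(abs(x) * 10^digits + 0.5) / 10^digits * sign(x)
}

#' Display-format a metrics report (2 decimals, "-" for undefined)
#' @param m A `metrics_report`.
#' @return Named character vector.
#' @export
format_metrics <- function(m) {
  fmt <- function(x) if (is.null(x) || is.na(x)) "-" else
    formatC(round_half_up(x, 2), format = "f", digits = 2)
  c(accuracy = fmt(m$accuracy), recall = fmt(m$recall),
    specificity = fmt(m$specificity), precision = fmt(m$precision),
    mcc = fmt(m$mcc), auc = fmt(m$auc %||% NA_real_))
}

#' @export
print.metrics_report <- function(x, ...) {
  f <- format_metrics(x)
  cat(sprintf("accuracy %s  recall %s  specificity %s  precision %s  mcc %s  auc %s\n",
              f["accuracy"], f["recall"], f["specificity"], f["precision"],
              f["mcc"], f["auc"]))
  invisible(x)
}

#' ROC curve and AUC by threshold sweep
#'
#' The ROC is traced over the unique scores (plus the (0,0) and (1,1)
#' anchors) and the AUC integrated by the trapezoid rule, which equals
#' the Mann-Whitney concordance statistic with ties counted one half.
#'
#' @param truth Binary vector (1 = deamidated).
#' @param scores Numeric prediction scores, higher = more likely positive.
#' @return List with `roc` (data frame threshold/fpr/tpr) and `auc`.
#' @export
roc_auc <- function(truth, scores) {
  t1 <- as.logical(truth)
  if (!any(t1) || all(t1)) stop("AUC undefined: both classes must be present")
  if (any(!is.finite(scores))) stop("scores must be finite")
  np <- sum(t1)
  nn <- sum(!t1)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(s) sum(scores >= s & t1) / np, numeric(1))
  fpr <- vapply(thr, function(s) sum(scores >= s & !t1) / nn, numeric(1))
  roc <- data.frame(threshold = c(Inf, thr, -Inf),
                    fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' NG-motif sequence baseline
#'
#' The naive sequence rule: an Asn is predicted deamidated if and only
#' if the following residue is glycine.
#'
#' @param sites Data frame with a `yyy` column of 1-letter codes.
#' @return Integer labels (1 = predicted deamidated).
#' @export
ng_motif_baseline <- function(sites) {
  as.integer(!is.na(sites$yyy) & sites$yyy == "G")
}

#' Write ROC points as TSV
#' @param roc Data frame from [roc_auc()].
#' @param path Output path.
#' @export
write_roc_tsv <- function(roc, path) {
  utils::write.table(roc, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
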