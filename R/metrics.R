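#' Per-class confusion summary
#'
#' Tabulates true positives, false positives and false negatives per class,
#' together with the class weights w_i (each class's share of the true
#' sample count). Classes listed in `class_names` but absent from both label
#' vectors get zero counts and weight zero.
#'
#' @param true_labels,pred_labels equal-length character vectors.
#' @param class_names ordered class set; every label must be a member.
#' @return object of class `confusion_summary`: data frame with one row per
#'   class (`class`, `tp`, `fp`, `fn`, `weight`) plus attribute `n`.
#' @export
confusion <- function(true_labels, pred_labels,
                      class_names = sort(unique(c(true_labels, pred_labels)))) {
  true_labels <- as.character(true_labels)
  pred_labels <- as.character(pred_labels)
  if (length(true_labels) != length(pred_labels) || !length(true_labels)) {
    stop("true and predicted label vectors must be nonempty and equal length")
  }
  bad <- setdiff(unique(c(true_labels, pred_labels)), class_names)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  tf <- factor(true_labels, levels = class_names)
  pf <- factor(pred_labels, levels = class_names)
  tab <- table(true = tf, pred = pf)
  tp <- diag(tab)
  fp <- colSums(tab) - tp
  fn <- rowSums(tab) - tp
  n <- length(true_labels)
  out <- data.frame(class = class_names,
                    tp = as.integer(tp), fp = as.integer(fp),
                    fn = as.integer(fn),
                    weight = as.numeric(rowSums(tab)) / n,
                    row.names = NULL)
  attr(out, "n") <- n
  class(out) <- c("confusion_summary", "data.frame")
  out
}

per_class_precision <- function(cs) {
  denom <- cs$tp + cs$fp
  p <- ifelse(denom > 0, cs$tp / denom, 0)  # zero-division convention
  p
}

per_class_recall <- function(cs) {
  denom <- cs$tp + cs$fn
  ifelse(denom > 0, cs$tp / denom, 0)
}

per_class_f1 <- function(cs) {
  p <- per_class_precision(cs)
  r <- per_class_recall(cs)
  ifelse(p + r > 0, 2 * p * r / (p + r), 0)
}

#' Weighted F1: harmonic mean of class-share-weighted precision and recall
#'
#' The score is `2 P_w R_w / (P_w + R_w)` where `P_w = sum_i w_i Precision_i`
#' and `R_w = sum_i w_i Recall_i`, with w_i the class sample shares. Note
#' this is NOT the (more common) class-share-weighted average of per-class
#' F1 scores; that variant is available as [weighted_f1_classwise()]. A class
#' never predicted contributes precision 0 (logged zero-division convention);
#' if both weighted precision and recall are zero the score is defined as 0.
#'
#' @param summary a [confusion()] summary.
#' @return numeric in `[0, 1]`.
#' @export
weighted_f1 <- function(summary) {
  stopifnot(inherits(summary, "confusion_summary"))
  pw <- sum(per_class_precision(summary) * summary$weight)
  rw <- sum(per_class_recall(summary) * summary$weight)
  if (pw + rw == 0) {
    message("weighted_f1: degenerate case, weighted precision and recall both zero")
    return(0)
  }
  2 * pw * rw / (pw + rw)
}

#' Class-share-weighted average of per-class F1 (common "weighted F1" variant)
#' @param summary a [confusion()] summary.
#' @return numeric in `[0, 1]`.
#' @export
weighted_f1_classwise <- function(summary) {
  stopifnot(inherits(summary, "confusion_summary"))
  sum(per_class_f1(summary) * summary$weight)
}

#' Macro F1: unweighted mean of per-class F1 over all classes
#' @param summary a [confusion()] summary.
#' @return numeric in `[0, 1]`.
#' @export
macro_f1 <- function(summary) {
  stopifnot(inherits(summary, "confusion_summary"))
  mean(per_class_f1(summary))
}

#' Classification accuracy: share of correctly predicted samples
#' @param true_labels,pred_labels equal-length label vectors.
#' @return numeric in `[0, 1]`.
#' @export
acc <- function(true_labels, pred_labels) {
  if (length(true_labels) != length(pred_labels) || !length(true_labels)) {
    stop("true and predicted label vectors must be nonempty and equal length")
  }
  mean(as.character(true_labels) == as.character(pred_labels))
}

#' Multiclass Matthews correlation coefficient
#'
#' True and predicted labels are expanded into n x L one-hot indicator
#' matrices X and Y; the score is `cov(X, Y) / sqrt(cov(X, X) cov(Y, Y))`
#' where `cov(A, B)` is the sum over the L columns of the per-column sample
#' covariances (the R_K matrix-correlation construction). For L = 2 this
#' equals the classical binary MCC. A constant indicator matrix (zero
#' denominator) yields 0.
#'
#' @param true_labels,pred_labels equal-length label vectors.
#' @param class_names ordered class set.
#' @return numeric in `[-1, 1]`.
#' @export
mcc <- function(true_labels, pred_labels,
                class_names = sort(unique(c(true_labels, pred_labels)))) {
  true_labels <- as.character(true_labels)
  pred_labels <- as.character(pred_labels)
  if (length(true_labels) != length(pred_labels) || !length(true_labels)) {
    stop("true and predicted label vectors must be nonempty and equal length")
  }
  bad <- setdiff(unique(c(true_labels, pred_labels)), class_names)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  X <- stats::model.matrix(~ 0 + factor(true_labels, levels = class_names))
  Y <- stats::model.matrix(~ 0 + factor(pred_labels, levels = class_names))
  covsum <- function(A, B) sum(vapply(seq_len(ncol(A)), function(k) {
    stats::cov(A[, k], B[, k])
  }, numeric(1)))
  num <- covsum(X, Y)
  den <- sqrt(covsum(X, X) * covsum(Y, Y))
  if (!is.finite(den) || den == 0) {
    message("mcc: degenerate case, constant indicator matrix; returning 0")
    return(0)
  }
  num / den
}

#' Full metric report for one set of pooled predictions
#'
#' @param true_labels,pred_labels equal-length label vectors.
#' @param class_names ordered class set.
#' @return object of class `metric_report`: list with `weighted_f1`,
#'   `macro_f1`, `acc`, `mcc`, and per-class `precision`, `recall`, `f1`
#'   (named by class).
#' @export
metric_report <- function(true_labels, pred_labels,
                          class_names = sort(unique(c(true_labels, pred_labels)))) {
  cs <- confusion(true_labels, pred_labels, class_names)
  pc_p <- per_class_precision(cs)
  pc_r <- per_class_recall(cs)
  pc_f <- per_class_f1(cs)
  names(pc_p) <- names(pc_r) <- names(pc_f) <- cs$class
  structure(list(
    weighted_f1 = weighted_f1(cs),
    macro_f1 = macro_f1(cs),
    acc = acc(true_labels, pred_labels),
    mcc = mcc(true_labels, pred_labels, class_names),
    precision = pc_p, recall = pc_r, f1 = pc_f
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("metric_report: weighted_f1=%.4f macro_f1=%.4f acc=%.4f mcc=%.4f\n",
              x$weighted_f1, x$macro_f1, x$acc, x$mcc))
  invisible(x)
}

#' Serialize a metric report to JSON with stable key names
#' @param x a `metric_report`.
#' @return a JSON string.
#' @export
metric_report_json <- function(x) {
  stopifnot(inherits(x, "metric_report"))
  jsonlite::toJSON(list(
    weighted_f1 = x$weighted_f1, macro_f1 = x$macro_f1,
    acc = x$acc, mcc = x$mcc,
    per_class = list(precision = as.list(x$precision),
                     recall = as.list(x$recall),
                     f1 = as.list(x$f1))
  ), auto_unbox = TRUE, digits = NA)
}
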