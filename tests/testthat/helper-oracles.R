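# Independent brute-force oracles. These re-derive every metric from first
# principles (explicit confusion counting, hand-coded covariance sums) and
# share no code with the package implementations they check.

oracle_confusion_counts <- function(true, pred, classes) {
  out <- lapply(classes, function(cl) {
    tp <- 0L; fp <- 0L; fn <- 0L
    for (i in seq_along(true)) {
      if (true[i] == cl && pred[i] == cl) tp <- tp + 1L
      if (true[i] != cl && pred[i] == cl) fp <- fp + 1L
      if (true[i] == cl && pred[i] != cl) fn <- fn + 1L
    }
    c(tp = tp, fp = fp, fn = fn)
  })
  names(out) <- classes
  out
}

# literal evaluation of the weighted-F1 chain: per-class precision/recall,
# class-share weights, harmonic mean of the weighted averages
oracle_weighted_f1 <- function(true, pred, classes) {
  cc <- oracle_confusion_counts(true, pred, classes)
  n <- length(true)
  pw <- 0; rw <- 0
  for (cl in classes) {
    w <- sum(true == cl) / n
    tp <- cc[[cl]]["tp"]; fp <- cc[[cl]]["fp"]; fn <- cc[[cl]]["fn"]
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    pw <- pw + w * prec
    rw <- rw + w * rec
  }
  if (pw + rw == 0) return(0)
  unname(2 * pw * rw / (pw + rw))
}

oracle_macro_f1 <- function(true, pred, classes) {
  cc <- oracle_confusion_counts(true, pred, classes)
  f1s <- vapply(classes, function(cl) {
    tp <- cc[[cl]]["tp"]; fp <- cc[[cl]]["fp"]; fn <- cc[[cl]]["fn"]
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }, numeric(1))
  mean(f1s)
}

oracle_acc <- function(true, pred) sum(true == pred) / length(true)

# indicator-matrix MCC with hand-coded column covariance sums
oracle_mcc <- function(true, pred, classes) {
  n <- length(true)
  X <- matrix(0, n, length(classes))
  Y <- matrix(0, n, length(classes))
  for (i in seq_len(n)) {
    X[i, match(true[i], classes)] <- 1
    Y[i, match(pred[i], classes)] <- 1
  }
  colcov <- function(A, B) {
    s <- 0
    for (k in seq_len(ncol(A))) {
      am <- sum(A[, k]) / n; bm <- sum(B[, k]) / n
      s <- s + sum((A[, k] - am) * (B[, k] - bm)) / (n - 1)
    }
    s
  }
  den <- sqrt(colcov(X, X) * colcov(Y, Y))
  if (!is.finite(den) || den == 0) return(0)
  colcov(X, Y) / den
}

# classical binary MCC from a 2x2 table; NA-producing denominators map to 0
oracle_binary_mcc <- function(tp, tn, fp, fn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

# label vectors realizing a 2x2 confusion table
binary_labels_from_table <- function(tp, tn, fp, fn) {
  true <- c(rep("pos", tp), rep("pos", fn), rep("neg", tn), rep("neg", fp))
  pred <- c(rep("pos", tp), rep("neg", fn), rep("neg", tn), rep("pos", fp))
  list(true = true, pred = pred)
}
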