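#' Oblivious-tree multiclass gradient booster
#'
#' A compact gradient-boosting machine over oblivious (symmetric) decision
#' trees: at every depth level of a tree, a single (feature, threshold-bin)
#' split is shared by all nodes of that level, so a depth-d tree is a lookup
#' table over d binary tests. Continuous features are pre-binned into
#' quantile histograms. One regression tree is grown per class per round on
#' the softmax gradient/hessian; split quality is the usual second-order
#' gain; leaf values are Newton steps. Feature importance is the total gain
#' accumulated by each feature over all chosen splits.
#'
#' @param X numeric matrix (samples x features) with column names.
#' @param y factor of class labels.
#' @param n_rounds boosting rounds (default 40).
#' @param depth tree depth (default 4).
#' @param n_bins histogram bins per feature (default 16).
#' @param learning_rate shrinkage (default 0.3).
#' @param reg_lambda L2 leaf regularization (default 1).
#' @param seed integer seed (used only for tie-free reproducibility of the
#'   binning; the algorithm itself is deterministic).
#' @return list with `importance` (named numeric, total gain per feature)
#'   and `train_acc` (final training accuracy).
#' @export
oblivious_boost <- function(X, y, n_rounds = 40L, depth = 4L, n_bins = 16L,
                            learning_rate = 0.3, reg_lambda = 1,
                            seed = 1L) {
  n <- nrow(X); p <- ncol(X)
  K <- length(levels(y))
  stopifnot(K >= 2L, n >= 2L)
  B <- as.integer(n_bins)

  # quantile binning: bin index in 1..B per entry; constant features land in
  # a single bin and can never split
  Xb <- matrix(1L, n, p)
  for (j in seq_len(p)) {
    qs <- unique(stats::quantile(X[, j], probs = seq(0, 1, length.out = B + 1),
                                 names = FALSE, type = 7))
    if (length(qs) > 2L) {
      Xb[, j] <- findInterval(X[, j], qs[-c(1, length(qs))], left.open = FALSE) + 1L
    }
  }
  # sparse indicator over (feature, bin) pairs: one crossprod aggregates
  # gradient/hessian histograms for all features at once
  S <- Matrix::sparseMatrix(
    i = rep(seq_len(n), p),
    j = as.vector(t(t(Xb) + (seq_len(p) - 1L) * B)),
    x = 1, dims = c(n, p * B))

  Yh <- stats::model.matrix(~ 0 + y)  # n x K one-hot
  Fm <- matrix(0, n, K)
  importance <- stats::setNames(rep(0, p), colnames(X))

  for (round in seq_len(n_rounds)) {
    Pm <- exp(Fm - apply(Fm, 1, max))
    Pm <- Pm / rowSums(Pm)
    for (k in seq_len(K)) {
      g <- Pm[, k] - Yh[, k]
      h <- pmax(Pm[, k] * (1 - Pm[, k]), 1e-12)
      leaf <- rep(1L, n)
      n_leaves <- 1L
      for (lvl in seq_len(depth)) {
        # per-leaf histograms of g and h over every (feature, bin)
        GH <- matrix(0, p * B, 2L * n_leaves)
        for (l in seq_len(n_leaves)) {
          ind <- leaf == l
          if (!any(ind)) next
          GH[, (2L * l - 1L):(2L * l)] <-
            as.matrix(Matrix::crossprod(S, cbind(g * ind, h * ind)))
        }
        # candidate split "bin <= b": cumulative sums within each feature
        best_gain <- 0; best_j <- 0L; best_b <- 0L
        total_gain_curve <- numeric(B - 1L)
        gain_all <- matrix(0, B - 1L, p)
        for (l in seq_len(n_leaves)) {
          Gm <- matrix(GH[, 2L * l - 1L], B, p)
          Hm <- matrix(GH[, 2L * l], B, p)
          GL <- apply(Gm, 2, cumsum)[-B, , drop = FALSE]
          HL <- apply(Hm, 2, cumsum)[-B, , drop = FALSE]
          Gt <- matrix(colSums(Gm), B - 1L, p, byrow = TRUE)
          Ht <- matrix(colSums(Hm), B - 1L, p, byrow = TRUE)
          GR <- Gt - GL; HR <- Ht - HL
          gain_all <- gain_all +
            GL^2 / (HL + reg_lambda) + GR^2 / (HR + reg_lambda) -
            Gt^2 / (Ht + reg_lambda)
        }
        best <- which(gain_all == max(gain_all), arr.ind = TRUE)[1L, ]
        best_gain <- max(gain_all)
        if (!is.finite(best_gain) || best_gain <= 1e-10) break
        best_b <- as.integer(best[["row"]])
        best_j <- as.integer(best[["col"]])
        importance[best_j] <- importance[best_j] + best_gain
        goes_right <- Xb[, best_j] > best_b
        leaf <- 2L * (leaf - 1L) + 1L + goes_right
        n_leaves <- 2L * n_leaves
      }
      # Newton leaf values
      Gs <- tapply(g, factor(leaf, levels = seq_len(n_leaves)), sum,
                   default = 0)
      Hs <- tapply(h, factor(leaf, levels = seq_len(n_leaves)), sum,
                   default = 0)
      vals <- -as.numeric(Gs) / (as.numeric(Hs) + reg_lambda)
      vals[!is.finite(vals)] <- 0
      Fm[, k] <- Fm[, k] + learning_rate * vals[leaf]
    }
  }
  pred <- levels(y)[max.col(Fm, ties.method = "first")]
  list(importance = importance, train_acc = mean(pred == as.character(y)))
}

oblivious_importance <- function(X, y, seed) {
  fit <- oblivious_boost(X, y, seed = seed)
  out <- rep(0, ncol(X))
  out[match(names(fit$importance), colnames(X))] <- fit$importance
  out
}
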