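#' Parameters for Monte Carlo feature selection
#'
#' @param s number of random feature subsets (default 100).
#' @param m features per subset; default `min(ceiling(0.1 p), 500)` via
#'   [mcfs_params_default()].
#' @param t random train/test splits per subset (default 5).
#' @param train_fraction share of samples used for training in each split
#'   (default 0.66).
#' @param u exponent on the tree's held-out class-balanced accuracy
#'   (default 1).
#' @param v exponent on the relative node coverage (default 1).
#' @param seed integer seed.
#' @return object of class `mcfs_params`.
#' @export
mcfs_params <- function(s = 100L, m, t = 5L, train_fraction = 0.66,
                        u = 1, v = 1, seed = 1L) {
  params <- structure(list(s = as.integer(s), m = as.integer(m),
                           t = as.integer(t), train_fraction = train_fraction,
                           u = u, v = v, seed = as.integer(seed)),
                      class = "mcfs_params")
  if (params$s < 1L || params$t < 1L) stop("need s >= 1 and t >= 1")
  if (params$m < 1L) stop("m must be positive")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie in (0, 1)")
  }
  if (u < 0 || v < 0) stop("u and v must be nonnegative")
  params
}

#' Default MCFS parameters for a matrix with p genes
#' @param n_genes number of genes p.
#' @param seed integer seed.
#' @return an [mcfs_params()] with `m = min(ceiling(0.1 p), 500)`.
#' @export
mcfs_params_default <- function(n_genes, seed = 1L) {
  mcfs_params(m = min(ceiling(0.1 * n_genes), 500L), seed = seed)
}

#' Monte Carlo feature selection ranking
#'
#' For each of `s` random feature subsets of size `m` and each of `t` random
#' train/test splits, one decision tree is fitted on the training part
#' restricted to the subset. The relative importance of gene `g` is
#'
#' `RI_g = sum over trees tau (wAcc_tau)^u * sum over nodes of tau splitting
#' on g of IG(node) * (coverage(node) / coverage(root))^v`
#'
#' where `wAcc` is the tree's class-balanced accuracy (mean per-class recall)
#' on its held-out split, `IG` the information gain (bits) of the split and
#' `coverage` the number of training samples reaching the node. Genes never
#' sampled into any subset score exactly 0.
#'
#' @param matrix a [labeled_matrix()].
#' @param params an [mcfs_params()].
#' @param keep_trees if TRUE, attach per-tree details (fitted rpart objects,
#'   feature subsets, training indices, wAcc) as attribute `trees` for
#'   auditing.
#' @return a `ranked_list`.
#' @export
mcfs_rank <- function(matrix, params = mcfs_params_default(ncol(matrix$values)),
                      keep_trees = FALSE) {
  stopifnot(inherits(matrix, "labeled_matrix"))
  X <- matrix$values
  colnames(X) <- paste0("g", seq_len(ncol(X)))
  y <- factor(matrix$labels, levels = matrix$class_names)
  scores <- mcfs_scores(X, y, params, keep_trees = keep_trees)
  rl <- ranked_list("MCFS", matrix$gene_ids, scores)
  if (keep_trees) attr(rl, "trees") <- attr(scores, "trees")
  rl
}

mcfs_scores <- function(X, y, params, keep_trees = FALSE) {
  n <- nrow(X); p <- ncol(X)
  if (params$m > p) stop("m (", params$m, ") exceeds the number of genes (", p, ")")
  n_train <- max(2L, round(params$train_fraction * n))
  scores <- stats::setNames(rep(0, p), colnames(X))
  trees <- if (keep_trees) vector("list", params$s * params$t) else NULL
  ti <- 0L
  withr::with_seed(derive_seed(params$seed, "mcfs"), {
    for (si in seq_len(params$s)) {
      feats <- sort(sample.int(p, params$m))
      for (tj in seq_len(params$t)) {
        ti <- ti + 1L
        train <- sample.int(n, n_train)
        df_train <- data.frame(y = y[train],
                               X[train, feats, drop = FALSE],
                               check.names = FALSE)
        fit <- rpart::rpart(y ~ ., data = df_train, method = "class",
                            parms = list(split = "information"),
                            control = rpart::rpart.control(
                              cp = 0.01, xval = 0, maxcompete = 0,
                              maxsurrogate = 0))
        test <- setdiff(seq_len(n), train)
        df_test <- data.frame(X[test, feats, drop = FALSE],
                              check.names = FALSE)
        pred <- stats::predict(fit, df_test, type = "class")
        wacc <- balanced_accuracy(y[test], pred)
        stats_df <- tree_split_stats(fit, df_train[-1], df_train$y)
        if (nrow(stats_df)) {
          contrib <- wacc^params$u *
            tapply(stats_df$gain * (stats_df$coverage / n_train)^params$v,
                   stats_df$var, sum)
          scores[names(contrib)] <- scores[names(contrib)] + contrib
        }
        if (keep_trees) {
          trees[[ti]] <- list(fit = fit, features = feats, train = train,
                              wacc = wacc)
        }
      }
    }
  })
  if (keep_trees) attr(scores, "trees") <- trees
  scores
}

# mean per-class recall over the classes present in the reference labels
balanced_accuracy <- function(true, pred) {
  true <- as.character(true); pred <- as.character(pred)
  classes <- unique(true)
  mean(vapply(classes, function(cl) {
    mean(pred[true == cl] == cl)
  }, numeric(1)))
}
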