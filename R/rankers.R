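#' Names of the available feature rankers
#' @return character vector of the eight ranker names.
#' @export
ranker_names <- function() {
  c("Adaboost", "CatBoost", "ExtraTrees", "LASSO",
    "LightGBM", "MCFS", "RF", "XGBoost")
}

ranked_list <- function(ranker_name, gene_ids, scores) {
  stopifnot(length(gene_ids) == length(scores))
  ord <- order(-scores, gene_ids)  # ties broken by ascending gene id
  structure(data.frame(gene_id = gene_ids[ord], score = as.numeric(scores[ord]),
                       stringsAsFactors = FALSE),
            ranker_name = ranker_name,
            class = c("ranked_list", "data.frame"))
}

#' @export
print.ranked_list <- function(x, ...) {
  cat(sprintf("ranked_list (%s): %d genes, top: %s\n",
              attr(x, "ranker_name"), nrow(x),
              paste(utils::head(x$gene_id, 3), collapse = ", ")))
  invisible(x)
}

#' Rank all genes of a labeled matrix by one importance criterion
#'
#' Produces a full ordering of the genes (scores non-increasing, ties broken
#' by ascending gene identifier). Available rankers and their importance
#' scores, each run on the full dataset with pinned defaults:
#'
#' * `RF` — random forest (100 trees, sqrt(p) features per split), Gini
#'   impurity-decrease importance.
#' * `ExtraTrees` — extremely randomized trees (100 trees, no bootstrap,
#'   random split thresholds), impurity importance.
#' * `XGBoost` — level-wise gradient boosting (100 rounds, depth 6,
#'   softmax objective), total-gain importance.
#' * `LightGBM` — leaf-wise (loss-guided) histogram gradient boosting
#'   (100 rounds, 31 leaves), total-gain importance.
#' * `CatBoost` — oblivious-tree (symmetric-tree) gradient boosting
#'   implemented in this package ([oblivious_boost()]), total-gain
#'   importance.
#' * `Adaboost` — multiclass SAMME boosting over depth-3 CART learners
#'   implemented in this package, importance = boosting-weight-weighted
#'   impurity improvement.
#' * `LASSO` — one-vs-rest L1-penalized logistic models; score = largest
#'   absolute standardized coefficient over classes, at a regularization
#'   strength chosen by internal cross-validation.
#' * `MCFS` — Monte Carlo feature selection ([mcfs_rank()]).
#'
#' @param matrix a [labeled_matrix()] with at least two classes present.
#' @param ranker_name one of [ranker_names()].
#' @param seed integer seed; rankings are deterministic given it.
#' @param mcfs_params optional [mcfs_params()] override for the MCFS ranker.
#' @return a `ranked_list` data frame (`gene_id`, `score`).
#' @export
rank_features <- function(matrix, ranker_name, seed = 1L, mcfs_params = NULL) {
  stopifnot(inherits(matrix, "labeled_matrix"))
  if (length(unique(matrix$labels)) < 2L) {
    stop("matrix has a single class; ranking requires >= 2 classes")
  }
  if (!ranker_name %in% ranker_names()) {
    stop("unknown ranker '", ranker_name, "'; valid: ",
         paste(ranker_names(), collapse = ", "))
  }
  X <- matrix$values
  p <- ncol(X)
  colnames(X) <- paste0("g", seq_len(p))  # safe internal feature names
  y <- factor(matrix$labels, levels = matrix$class_names)
  rseed <- derive_seed(seed, "rank", match(ranker_name, ranker_names()))
  scores <- switch(
    ranker_name,
    RF = ranger_importance(X, y, rseed, extratrees = FALSE),
    ExtraTrees = ranger_importance(X, y, rseed, extratrees = TRUE),
    XGBoost = xgb_importance(X, y, rseed, leafwise = FALSE),
    LightGBM = xgb_importance(X, y, rseed, leafwise = TRUE),
    CatBoost = oblivious_importance(X, y, rseed),
    Adaboost = adaboost_importance(X, y, rseed),
    LASSO = lasso_importance(X, y, rseed),
    MCFS = {
      params <- mcfs_params %||% mcfs_params_default(p, seed = rseed)
      sc <- mcfs_scores(X, y, params)
      sc
    }
  )
  ranked_list(ranker_name, matrix$gene_ids, scores)
}

#' First k gene identifiers of a ranked list
#' @param list a `ranked_list`.
#' @param k prefix size, `1 <= k <= nrow(list)`.
#' @return character vector of the first `k` gene ids in rank order.
#' @export
top_prefix <- function(list, k) {
  stopifnot(inherits(list, "ranked_list"))
  if (length(k) != 1L || is.na(k) || k < 1L || k > nrow(list)) {
    stop("k must lie in 1..", nrow(list))
  }
  list$gene_id[seq_len(k)]
}

# --- ranger-backed rankers ------------------------------------------------

ranger_importance <- function(X, y, seed, extratrees = FALSE) {
  args <- list(x = as.data.frame(X), y = y, num.trees = 100L,
               importance = "impurity", seed = seed, num.threads = 1L,
               mtry = floor(sqrt(ncol(X))))
  if (extratrees) {
    args <- c(args, list(splitrule = "extratrees", num.random.splits = 1L,
                         replace = FALSE, sample.fraction = 1))
  }
  fit <- do.call(ranger::ranger, args)
  imp <- fit$variable.importance
  out <- rep(0, ncol(X))
  out[match(names(imp), colnames(X))] <- imp
  out
}

# --- xgboost-backed rankers ----------------------------------------------
# leafwise = TRUE grows trees by best-leaf-first (loss-guided) expansion over
# histogram bins, the growth strategy characteristic of light gradient
# boosting machines; leafwise = FALSE is conventional depth-wise growth.

xgb_importance <- function(X, y, seed, leafwise = FALSE) {
  num_class <- length(levels(y))
  params <- list(objective = "multi:softprob", num_class = num_class,
                 eta = 0.3, nthread = 1, seed = seed,
                 tree_method = "hist")
  if (leafwise) {
    params$grow_policy <- "lossguide"
    params$max_leaves <- 31
    params$max_depth <- 0
    params$eta <- 0.1
  } else {
    params$max_depth <- 6
  }
  dtrain <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L)
  set.seed(seed)
  fit <- xgboost::xgb.train(params = params, data = dtrain, nrounds = 100L,
                            verbose = 0)
  imp <- xgboost::xgb.importance(model = fit)
  out <- rep(0, ncol(X))
  out[match(imp$Feature, colnames(X))] <- imp$Gain
  out
}

# --- multiclass AdaBoost (SAMME) over shallow CART learners ---------------

adaboost_importance <- function(X, y, seed, n_rounds = 50L, max_depth = 3L) {
  n <- nrow(X)
  K <- length(levels(y))
  df <- data.frame(y = y, as.data.frame(X))
  w <- rep(1 / n, n)
  imp <- stats::setNames(rep(0, ncol(X)), colnames(X))
  withr::with_seed(seed, {
    for (m in seq_len(n_rounds)) {
      fit <- rpart::rpart(y ~ ., data = df, weights = w, method = "class",
                          control = rpart::rpart.control(
                            maxdepth = max_depth, cp = 0, xval = 0,
                            maxcompete = 0, maxsurrogate = 0))
      pred <- stats::predict(fit, df, type = "class")
      miss <- pred != y
      err <- sum(w[miss]) / sum(w)
      if (err <= 0) {
        vi <- fit$variable.importance
        if (!is.null(vi)) imp[names(vi)] <- imp[names(vi)] + vi
        break
      }
      if (err >= 1 - 1 / K) break  # weak-learner condition violated
      alpha <- log((1 - err) / err) + log(K - 1)
      vi <- fit$variable.importance
      if (!is.null(vi)) imp[names(vi)] <- imp[names(vi)] + alpha * vi
      w <- w * exp(alpha * miss)
      w <- w / sum(w)
    }
  })
  unname(imp)
}

# --- LASSO (one-vs-rest L1 logistic regression) ---------------------------

lasso_importance <- function(X, y, seed) {
  classes <- levels(y)
  n <- nrow(X)
  foldid <- withr::with_seed(derive_seed(seed, "lasso"),
                             sample(rep_len(1:3, n)))
  score <- rep(0, ncol(X))
  for (cl in classes) {
    yc <- as.integer(y == cl)
    cv <- glmnet::cv.glmnet(X, yc, family = "binomial", alpha = 1,
                            foldid = foldid, standardize = TRUE)
    beta <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1]  # drop intercept
    score <- pmax(score, abs(beta))
  }
  score
}
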