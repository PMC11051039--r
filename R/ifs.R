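#' Prefix sizes for an incremental feature-selection sweep
#'
#' Sizes are `step, 2 step, ...` up to the largest multiple of `step` not
#' exceeding `top_n`; `top_n` itself is appended when it is not a multiple.
#' If `step > top_n` the single size `top_n` is returned.
#'
#' @param top_n largest prefix size considered.
#' @param step spacing between successive sizes.
#' @return increasing integer vector of prefix sizes.
#' @export
build_subset_sizes <- function(top_n, step) {
  if (length(top_n) != 1L || length(step) != 1L ||
      is.na(top_n) || is.na(step) || top_n < 1L || step < 1L) {
    stop("top_n and step must be positive integers")
  }
  sizes <- if (step > top_n) integer(0) else seq.int(step, top_n, by = step)
  if (!length(sizes) || sizes[length(sizes)] != top_n) {
    sizes <- c(sizes, top_n)
  }
  as.integer(sizes)
}

fit_ifs_classifier <- function(classifier_name, X, y, seed) {
  if (classifier_name == "DT") {
    df <- data.frame(y = y, as.data.frame(X))
    fit <- rpart::rpart(y ~ ., data = df, method = "class",
                        control = rpart::rpart.control(
                          cp = 0, minsplit = 2, minbucket = 1,
                          maxdepth = 30, xval = 0,
                          maxcompete = 0, maxsurrogate = 0))
    structure(list(fit = fit), class = "ifs_dt")
  } else if (classifier_name == "RF") {
    fit <- ranger::ranger(x = as.data.frame(X), y = y, num.trees = 100L,
                          mtry = max(1L, floor(sqrt(ncol(X)))),
                          seed = seed, num.threads = 1L)
    structure(list(fit = fit), class = "ifs_rf")
  } else {
    stop("unknown classifier '", classifier_name, "'; valid: DT, RF")
  }
}

predict_ifs_classifier <- function(model, X) {
  df <- as.data.frame(X)
  if (inherits(model, "ifs_dt")) {
    as.character(stats::predict(model$fit, df, type = "class"))
  } else {
    as.character(stats::predict(model$fit, data = df,
                                num.threads = 1L)$predictions)
  }
}

# deterministic stratified fold assignment; errors when any class present
# has fewer samples than folds (a fold would lack that class)
stratified_folds <- function(labels, folds, seed) {
  counts <- table(labels)
  lacking <- names(counts)[counts < folds]
  if (length(lacking)) {
    stop("class '", lacking[1], "' has ", counts[lacking[1]],
         " samples, fewer than ", folds,
         " folds; some folds would lack it - use fewer folds")
  }
  assignment <- integer(length(labels))
  withr::with_seed(derive_seed(seed, "fold"), {
    for (cl in names(counts)) {
      idx <- sample(which(labels == cl))
      assignment[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assignment
}

#' Evaluate one feature subset with SMOTE-balanced cross-validation
#'
#' Stratified k-fold split; within each fold, the training data restricted
#' to `gene_subset` is SMOTE-balanced, the classifier is fitted on the
#' balanced set, and the (untouched, never synthetic) evaluation-fold
#' samples are predicted. Predictions are pooled over folds — every sample
#' is predicted exactly once — and scored with the metrics module.
#'
#' @param matrix a [labeled_matrix()].
#' @param gene_subset character vector of gene ids (subset of the matrix).
#' @param classifier_name "DT" (CART, Gini, unlimited depth) or "RF"
#'   (100 trees, sqrt(d) features per split).
#' @param folds number of cross-validation folds (default 10).
#' @param smote_k SMOTE neighbor count (default 5).
#' @param seed integer seed.
#' @return object of class `ifs_record`: list with `k`, `classifier_name`,
#'   `report` (a [metric_report()]) and `pooled_pred`.
#' @export
evaluate_subset <- function(matrix, gene_subset, classifier_name = "RF",
                            folds = 10L, smote_k = 5L, seed = 1L) {
  stopifnot(inherits(matrix, "labeled_matrix"))
  if (folds < 2L) stop("folds must be >= 2")
  missing_genes <- setdiff(gene_subset, matrix$gene_ids)
  if (length(missing_genes)) {
    stop("gene_subset contains genes absent from the matrix: ",
         paste(utils::head(missing_genes, 3), collapse = ", "))
  }
  cols <- match(gene_subset, matrix$gene_ids)
  X <- matrix$values[, cols, drop = FALSE]
  colnames(X) <- paste0("g", seq_along(cols))
  y <- matrix$labels
  fold_of <- stratified_folds(y, folds, seed)
  pred <- character(length(y))
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    bal <- smote_balance(X[tr, , drop = FALSE], y[tr], k_neighbors = smote_k,
                         seed = derive_seed(seed, "fold", f))
    model <- fit_ifs_classifier(classifier_name, bal$values,
                                factor(bal$labels, levels = matrix$class_names),
                                seed = derive_seed(seed, "fold", f + 1000L))
    pred[!tr] <- predict_ifs_classifier(model, X[!tr, , drop = FALSE])
  }
  report <- metric_report(y, pred, matrix$class_names)
  structure(list(k = length(gene_subset), classifier_name = classifier_name,
                 report = report, pooled_pred = pred),
            class = "ifs_record")
}

#' Run an incremental feature-selection sweep over one ranked list
#'
#' Evaluates the nested prefixes of the ranked list at every size from
#' [build_subset_sizes()] via [evaluate_subset()], producing one curve for
#' one (feature list, classifier) pair.
#'
#' @param matrix a [labeled_matrix()].
#' @param ranked_list a `ranked_list` covering the matrix genes.
#' @param classifier_name "DT" or "RF".
#' @param config a [pipeline_config()] supplying `top_n`, `step`,
#'   `cv_folds`, `smote_k` and `seed`.
#' @return object of class `ifs_curve`: data frame with one row per prefix
#'   size (columns `ranker`, `classifier`, `k`, `weighted_f1`, `macro_f1`,
#'   `acc`, `mcc`, `f1_<class>` per class), with the evaluated gene prefix
#'   order as attribute `gene_ids`.
#' @export
run_ifs <- function(matrix, ranked_list, classifier_name = "RF",
                    config = pipeline_config()) {
  stopifnot(inherits(ranked_list, "ranked_list"))
  if (!all(matrix$gene_ids %in% ranked_list$gene_id)) {
    stop("ranked list does not cover the matrix genes")
  }
  t0 <- Sys.time()
  top_n <- min(config$top_n, nrow(ranked_list))
  sizes <- build_subset_sizes(top_n, config$step)
  rows <- lapply(sizes, function(k) {
    rec <- evaluate_subset(matrix, top_prefix(ranked_list, k),
                           classifier_name, folds = config$cv_folds,
                           smote_k = config$smote_k,
                           seed = derive_seed(config$seed, "ifs", k))
    r <- rec$report
    cbind(data.frame(ranker = attr(ranked_list, "ranker_name"),
                     classifier = classifier_name, k = k,
                     weighted_f1 = r$weighted_f1, macro_f1 = r$macro_f1,
                     acc = r$acc, mcc = r$mcc),
          stats::setNames(as.data.frame(t(r$f1)),
                          paste0("f1_", names(r$f1))))
  })
  curve <- do.call(rbind, rows)
  log_stage("ifs", t0, ranker = attr(ranked_list, "ranker_name"),
            classifier = classifier_name, points = nrow(curve),
            n = nrow(matrix$values))
  structure(curve, gene_ids = top_prefix(ranked_list, top_n),
            class = c("ifs_curve", "data.frame"))
}

#' Construct an IFS curve from bare k/score pairs
#'
#' Convenience constructor for selection-stage analyses of externally
#' produced curves (e.g. published values) where only prefix sizes and
#' weighted F1 scores are known.
#'
#' @param k integer vector of prefix sizes (strictly increasing).
#' @param weighted_f1 numeric vector of scores.
#' @param ranker,classifier names recorded on the curve.
#' @param gene_ids optional gene order underlying the prefixes.
#' @return an `ifs_curve`.
#' @export
ifs_curve <- function(k, weighted_f1, ranker = "manual", classifier = "RF",
                      gene_ids = NULL) {
  stopifnot(length(k) == length(weighted_f1), !is.unsorted(k, strictly = TRUE))
  structure(data.frame(ranker = ranker, classifier = classifier, k = k,
                       weighted_f1 = weighted_f1),
            gene_ids = gene_ids, class = c("ifs_curve", "data.frame"))
}
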