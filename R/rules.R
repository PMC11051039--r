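#' Extract threshold classification rules from a decision tree
#'
#' The full dataset restricted to `gene_subset` is SMOTE-balanced, one CART
#' decision tree is fitted on the balanced data, and every root-to-leaf path
#' is rendered as a conjunction of threshold predicates (`gene <= t` /
#' `gene > t`) predicting the leaf's majority class. Redundant predicates on
#' the same gene and side are merged into the tightest bound. The rule set
#' partitions feature space: any input vector satisfies exactly one rule.
#'
#' @param matrix a [labeled_matrix()].
#' @param gene_subset nonempty character vector of gene ids.
#' @param smote_k SMOTE neighbor count (default 5).
#' @param seed integer seed.
#' @param max_depth maximum tree depth (default 30, rpart's hard cap, i.e.
#'   effectively unpruned); lower it to trade rule count for readability.
#' @param minsplit minimum node size eligible for splitting (default 20).
#' @return object of class `rule_set`: list of rules, each with
#'   `predicates` (data frame `gene_id`, `op` in `<=`/`>`, `threshold`),
#'   `predicted_class`, `support` (named per-class training counts at the
#'   leaf, balanced data) and `purity`.
#' @export
extract_rules <- function(matrix, gene_subset, smote_k = 5L, seed = 1L,
                          max_depth = 30L, minsplit = 20L) {
  stopifnot(inherits(matrix, "labeled_matrix"), length(gene_subset) > 0)
  cols <- match(gene_subset, matrix$gene_ids)
  if (anyNA(cols)) stop("gene_subset contains genes absent from the matrix")
  X <- matrix$values[, cols, drop = FALSE]
  safe <- paste0("g", seq_along(cols))
  colnames(X) <- safe
  bal <- smote_balance(X, matrix$labels, k_neighbors = smote_k,
                       seed = derive_seed(seed, "rules"))
  y <- factor(bal$labels, levels = matrix$class_names)
  df <- data.frame(y = y, as.data.frame(bal$values))
  fit <- rpart::rpart(y ~ ., data = df, method = "class",
                      control = rpart::rpart.control(
                        cp = 0, minsplit = minsplit, maxdepth = max_depth,
                        xval = 0, maxcompete = 0, maxsurrogate = 0))
  tree_df <- parse_tree(fit)
  frame <- fit$frame
  L <- length(matrix$class_names)
  counts_mat <- frame$yval2[, 1L + seq_len(L), drop = FALSE]
  leaves <- tree_df$node[tree_df$is_leaf]
  name_of <- stats::setNames(gene_subset, safe)
  rules <- lapply(leaves, function(leaf) {
    preds <- path_predicates(tree_df, leaf)
    if (nrow(preds)) preds$gene_id <- unname(name_of[preds$var])
    support <- counts_mat[which(tree_df$node == leaf), ]
    names(support) <- matrix$class_names
    structure(list(
      predicates = merge_predicates(preds),
      predicted_class = matrix$class_names[which.max(support)],
      support = support,
      purity = max(support) / sum(support)
    ), class = "rule")
  })
  structure(rules, class = "rule_set",
            gene_subset = gene_subset, classes = matrix$class_names)
}

# predicates along the root-to-leaf path, in root-to-leaf order; rpart's
# "x < t" left branches become "x <= t" (thresholds are midpoints between
# observed values, so the closed bound matches the tree on any training or
# generic continuous input)
path_predicates <- function(tree_df, leaf) {
  steps <- list()
  node <- leaf
  while (node > 1L) {
    parent <- node %/% 2L
    prow <- tree_df[tree_df$node == parent, ]
    went_left <- node %% 2L == 0L
    # left_lt: left child takes x < t; otherwise left takes x >= t
    le <- (prow$left_lt & went_left) | (!prow$left_lt & !went_left)
    steps[[length(steps) + 1L]] <-
      data.frame(var = prow$var, op = if (le) "<=" else ">",
                 threshold = prow$threshold, stringsAsFactors = FALSE)
    node <- parent
  }
  if (!length(steps)) {
    return(data.frame(var = character(), op = character(),
                      threshold = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rev(steps))
}

# tightest bound per (gene, side): min of the "<=" thresholds, max of ">"
merge_predicates <- function(preds) {
  if (!nrow(preds)) {
    return(data.frame(gene_id = character(), op = character(),
                      threshold = numeric(), stringsAsFactors = FALSE))
  }
  key <- paste(preds$gene_id, preds$op)
  out <- do.call(rbind, lapply(unique(key), function(kk) {
    grp <- preds[key == kk, , drop = FALSE]
    thr <- if (grp$op[1] == "<=") min(grp$threshold) else max(grp$threshold)
    data.frame(gene_id = grp$gene_id[1], op = grp$op[1], threshold = thr,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Apply a rule set to a matrix of inputs
#'
#' @param rules a `rule_set`.
#' @param values numeric matrix with columns named (or ordered) as the rule
#'   set's `gene_subset`.
#' @return list with `class` (predicted class per row) and `rule_index`
#'   (which rule matched); errors if any row matches zero or multiple rules.
#' @export
apply_rules <- function(rules, values) {
  stopifnot(inherits(rules, "rule_set"))
  genes <- attr(rules, "gene_subset")
  values <- as.matrix(values)
  if (is.null(colnames(values))) colnames(values) <- genes
  match_mat <- vapply(rules, function(rule) {
    ok <- rep(TRUE, nrow(values))
    p <- rule$predicates
    for (i in seq_len(nrow(p))) {
      x <- values[, p$gene_id[i]]
      ok <- ok & if (p$op[i] == "<=") x <= p$threshold[i] else x > p$threshold[i]
    }
    ok
  }, logical(nrow(values)))
  match_mat <- matrix(match_mat, nrow = nrow(values))
  hits <- rowSums(match_mat)
  if (any(hits != 1L)) {
    stop("rule set does not partition the input: row ",
         which(hits != 1L)[1], " matched ", hits[hits != 1L][1], " rules")
  }
  idx <- max.col(match_mat, ties.method = "first")
  list(class = vapply(rules, `[[`, "", "predicted_class")[idx],
       rule_index = idx)
}

#' Number of rules per predicted class
#' @param rules a `rule_set`.
#' @return named integer vector over the class set (zero for classes with no
#'   rules).
#' @export
rule_counts <- function(rules) {
  stopifnot(inherits(rules, "rule_set"), length(rules) > 0)
  classes <- attr(rules, "classes")
  pred <- vapply(rules, `[[`, "", "predicted_class")
  counts <- table(factor(pred, levels = classes))
  stats::setNames(as.integer(counts), classes)
}

#' Render rules as human-readable text
#' @param rules a `rule_set`.
#' @param digits significant digits for thresholds (default 4).
#' @return character vector, one "IF ... THEN ..." line per rule.
#' @export
format_rules <- function(rules, digits = 4) {
  vapply(rules, function(rule) {
    p <- rule$predicates
    cond <- if (nrow(p)) {
      paste(sprintf("%s %s %s", p$gene_id, p$op,
                    signif(p$threshold, digits)), collapse = " AND ")
    } else "TRUE"
    sprintf("IF %s THEN %s (purity %.2f)", cond, rule$predicted_class,
            rule$purity)
  }, character(1))
}

#' @export
print.rule_set <- function(x, ...) {
  cat(sprintf("rule_set: %d rules over %d genes\n", length(x),
              length(attr(x, "gene_subset"))))
  cat(utils::head(format_rules(x), 5), sep = "\n")
  if (length(x) > 5) cat("...\n")
  invisible(x)
}
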