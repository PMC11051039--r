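essential_subset <- function(curve, k, point_kind) {
  row <- curve[curve$k == k, , drop = FALSE]
  gene_ids <- attr(curve, "gene_ids")
  structure(list(ranker_name = row$ranker[1], classifier_name = row$classifier[1],
                 point_kind = point_kind, k = k,
                 score = row$weighted_f1[1],
                 gene_ids = if (!is.null(gene_ids)) gene_ids[seq_len(k)] else NULL),
            class = "essential_subset")
}

#' @export
print.essential_subset <- function(x, ...) {
  cat(sprintf("essential_subset (%s/%s): %s point at k=%d, weighted F1 %.4f\n",
              x$ranker_name, x$classifier_name, x$point_kind, x$k, x$score))
  invisible(x)
}

#' Maximum point of an IFS curve
#'
#' Returns the smallest prefix size achieving the maximum weighted F1
#' (parsimony tie-break).
#'
#' @param curve an `ifs_curve`.
#' @return an `essential_subset` with `point_kind = "max"`.
#' @export
find_max_point <- function(curve) {
  stopifnot(inherits(curve, "ifs_curve"), nrow(curve) > 0)
  best <- max(curve$weighted_f1)
  k <- min(curve$k[curve$weighted_f1 == best])
  essential_subset(curve, k, "max")
}

#' Relatively high point of an IFS curve
#'
#' When the maximum point needs at least `k_threshold` features, the
#' relatively high point is the smallest prefix size whose weighted F1 is
#' within `delta` of the maximum. Returns `NULL` when the maximum needs
#' fewer than `k_threshold` features, or when no strictly smaller prefix
#' qualifies.
#'
#' @param curve an `ifs_curve`.
#' @param delta tolerated drop below the maximum weighted F1 (default 0.015).
#' @param k_threshold minimum max-point size for a relative point to be
#'   sought (default 100).
#' @return an `essential_subset` with `point_kind = "relative_high"`, or
#'   `NULL`.
#' @export
find_relative_high_point <- function(curve, delta = 0.015, k_threshold = 100L) {
  stopifnot(inherits(curve, "ifs_curve"), nrow(curve) > 0, delta >= 0)
  mx <- find_max_point(curve)
  if (mx$k < k_threshold) return(NULL)
  ok <- curve$k[curve$weighted_f1 >= mx$score - delta]
  k <- min(ok)
  if (k >= mx$k) return(NULL)
  essential_subset(curve, k, "relative_high")
}

#' Essential feature subsets across a family of IFS curves
#'
#' For each curve the maximum point is taken, replaced by its relatively
#' high point when one exists — the smaller subset is the "essential" one
#' carried into the consensus analysis.
#'
#' @param curves list of `ifs_curve` objects (one per ranker, all from the
#'   chosen classifier).
#' @param config a [pipeline_config()] supplying `relative_delta` and
#'   `relative_k_threshold`.
#' @return list of `essential_subset` objects, one per curve.
#' @export
essential_subsets <- function(curves, config = pipeline_config()) {
  lapply(curves, function(curve) {
    rel <- find_relative_high_point(curve, config$relative_delta,
                                    config$relative_k_threshold)
    rel %||% find_max_point(curve)
  })
}

#' Consensus of essential subsets across rankers
#'
#' Tabulates, for every gene selected by at least one essential subset, how
#' many subsets selected it and which — the selection-frequency view — and
#' the upset-style tabulation: for every nonempty combination of subsets,
#' the number of genes selected by exactly that combination.
#'
#' @param subsets list of `essential_subset` objects with non-NULL
#'   `gene_ids`.
#' @return object of class `consensus_table`: list with `genes` (data frame
#'   `gene_id`, `count`, `lists`) and `upset` (data frame `combination`,
#'   `size`, combinations as "/"-joined sorted ranker names).
#' @export
consensus <- function(subsets) {
  stopifnot(length(subsets) >= 1)
  names(subsets) <- vapply(subsets, `[[`, "", "ranker_name")
  membership <- lapply(subsets, `[[`, "gene_ids")
  if (any(vapply(membership, is.null, logical(1)))) {
    stop("every essential subset needs gene_ids for consensus")
  }
  genes <- sort(unique(unlist(membership)))
  in_list <- vapply(membership, function(g) genes %in% g,
                    logical(length(genes)))
  in_list <- matrix(in_list, nrow = length(genes),
                    dimnames = list(genes, names(subsets)))
  counts <- rowSums(in_list)
  lists <- apply(in_list, 1L, function(row) {
    paste(sort(colnames(in_list)[row]), collapse = "/")
  })
  gene_df <- data.frame(gene_id = genes, count = as.integer(counts),
                        lists = unname(lists), stringsAsFactors = FALSE)
  up <- as.data.frame(table(lists), stringsAsFactors = FALSE)
  names(up) <- c("combination", "size")
  up <- up[order(-up$size, up$combination), ]
  rownames(up) <- NULL
  structure(list(genes = gene_df, upset = up), class = "consensus_table")
}

#' @export
print.consensus_table <- function(x, ...) {
  cat(sprintf("consensus_table: %d genes over %d exact combinations; max count %d\n",
              nrow(x$genes), nrow(x$upset), max(x$genes$count)))
  invisible(x)
}
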