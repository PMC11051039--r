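#' Run the full marker-discovery pipeline on a labeled matrix
#'
#' Executes, in order: feature ranking (one list per configured ranker),
#' IFS sweeps (one curve per list and configured classifier), essential
#' subset extraction on the selection classifier's curves, cross-ranker
#' consensus, and rule extraction (one decision-tree rule set per ranker's
#' essential subset).
#'
#' @param matrix a [labeled_matrix()].
#' @param config a [pipeline_config()].
#' @return object of class `ifs_pipeline_result`: list with `ranked_lists`,
#'   `curves` (named `<ranker>_<classifier>`), `essential`, `consensus`,
#'   `rules` (per ranker), `rule_count_table` and `config`.
#' @export
run_pipeline <- function(matrix, config = pipeline_config()) {
  stopifnot(inherits(matrix, "labeled_matrix"))
  validate_pipeline_config(config)
  t0 <- Sys.time()
  ranked_lists <- lapply(config$rankers, function(rk) {
    t1 <- Sys.time()
    rl <- rank_features(matrix, rk, seed = config$seed)
    log_stage("rank", t1, ranker = rk, genes = nrow(rl))
    rl
  })
  names(ranked_lists) <- config$rankers

  curves <- list()
  for (rk in config$rankers) {
    for (cls in config$classifiers) {
      curves[[paste(rk, cls, sep = "_")]] <-
        run_ifs(matrix, ranked_lists[[rk]], cls, config)
    }
  }

  sel_curves <- curves[paste(config$rankers, config$selection_classifier,
                             sep = "_")]
  essential <- essential_subsets(sel_curves, config)
  names(essential) <- config$rankers
  cons <- consensus(essential)

  rules <- lapply(essential, function(s) {
    extract_rules(matrix, s$gene_ids, smote_k = config$smote_k,
                  seed = config$seed)
  })
  rule_count_table <- do.call(rbind, lapply(names(rules), function(rk) {
    data.frame(ranker = rk, t(rule_counts(rules[[rk]])),
               check.names = FALSE)
  }))
  log_stage("pipeline", t0, cells = nrow(matrix$values),
            genes = ncol(matrix$values), rankers = length(config$rankers))
  structure(list(ranked_lists = ranked_lists, curves = curves,
                 essential = essential, consensus = cons, rules = rules,
                 rule_count_table = rule_count_table, config = config),
            class = "ifs_pipeline_result")
}

#' Write every artifact of a pipeline result into a directory
#'
#' Produces the on-disk layout the numbered analysis scripts and the report
#' aggregator consume: per-ranker feature lists and rule files, per-curve
#' CSVs, essential subset CSVs, the consensus table and a single JSON
#' summary.
#'
#' @param result an `ifs_pipeline_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  stopifnot(inherits(result, "ifs_pipeline_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rk in names(result$ranked_lists)) {
    write_ranked_list(result$ranked_lists[[rk]],
                      file.path(dir, paste0("features_", rk, ".csv")))
  }
  for (nm in names(result$curves)) {
    write_curve(result$curves[[nm]], file.path(dir, paste0("curve_", nm, ".csv")))
  }
  write_subsets(result$essential, file.path(dir, "essential"))
  write_consensus(result$consensus, file.path(dir, "consensus_genes.csv"),
                  file.path(dir, "consensus_upset.json"))
  for (rk in names(result$rules)) {
    write_rules(result$rules[[rk]],
                file.path(dir, paste0("rules_", rk, ".csv")),
                file.path(dir, paste0("rules_", rk, ".json")))
  }
  data.table::fwrite(result$rule_count_table,
                     file.path(dir, "rule_counts.csv"))
  jsonlite::write_json(pipeline_summary(result),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Aggregate a pipeline result into one JSON-ready summary
#'
#' @param result an `ifs_pipeline_result`.
#' @return a named list: per-ranker best points, essential subset sizes,
#'   consensus top genes, and per-class rule counts.
#' @export
pipeline_summary <- function(result) {
  stopifnot(inherits(result, "ifs_pipeline_result"))
  ess <- lapply(result$essential, function(s) {
    list(point_kind = s$point_kind, k = s$k, weighted_f1 = s$score)
  })
  best <- lapply(result$curves, function(curve) {
    mx <- find_max_point(curve)
    list(k = mx$k, weighted_f1 = mx$score)
  })
  list(
    config = unclass(result$config),
    best_points = best,
    essential_subsets = ess,
    consensus = list(
      n_genes = nrow(result$consensus$genes),
      max_count = max(result$consensus$genes$count),
      top_genes = utils::head(
        result$consensus$genes[order(-result$consensus$genes$count,
                                     result$consensus$genes$gene_id), ], 20)
    ),
    rule_counts = result$rule_count_table
  )
}
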