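# Writers/readers for the pipeline's tabular artifacts. Everything is plain
# CSV or JSON so runs diff cleanly.

#' Write a ranked feature list as two-column CSV (gene_id, score)
#' @param list a `ranked_list`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ranked_list <- function(list, path) {
  stopifnot(inherits(list, "ranked_list"))
  data.table::fwrite(data.frame(gene_id = list$gene_id, score = list$score),
                     path)
  invisible(path)
}

#' Read a ranked feature list written by [write_ranked_list()]
#' @param path CSV path.
#' @param ranker_name name recorded on the returned list.
#' @return a `ranked_list`.
#' @export
read_ranked_list <- function(path, ranker_name = "unknown") {
  df <- data.table::fread(path, data.table = FALSE)
  ranked_list(ranker_name, df$gene_id, df$score)
}

#' Write an IFS curve as CSV
#' @param curve an `ifs_curve`.
#' @param path output CSV path; the evaluated gene order goes to
#'   `<path>.genes.txt` when present.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "ifs_curve"))
  data.table::fwrite(as.data.frame(curve), path)
  if (!is.null(attr(curve, "gene_ids"))) {
    writeLines(attr(curve, "gene_ids"), paste0(path, ".genes.txt"))
  }
  invisible(path)
}

#' Read an IFS curve written by [write_curve()]
#' @param path CSV path.
#' @return an `ifs_curve`.
#' @export
read_curve <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  genes_path <- paste0(path, ".genes.txt")
  structure(df,
            gene_ids = if (file.exists(genes_path)) readLines(genes_path),
            class = c("ifs_curve", "data.frame"))
}

#' Write essential subsets (one CSV per subset: gene_id, rank)
#' @param subsets list of `essential_subset` objects.
#' @param dir output directory (created if needed).
#' @return the written paths, invisibly.
#' @export
write_subsets <- function(subsets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(subsets, function(s) {
    path <- file.path(dir, paste0("essential_", s$ranker_name, ".csv"))
    data.table::fwrite(data.frame(gene_id = s$gene_ids,
                                  rank = seq_along(s$gene_ids)), path)
    path
  }, character(1))
  meta <- data.frame(
    ranker = vapply(subsets, `[[`, "", "ranker_name"),
    classifier = vapply(subsets, `[[`, "", "classifier_name"),
    point_kind = vapply(subsets, `[[`, "", "point_kind"),
    k = vapply(subsets, `[[`, 0, "k"),
    weighted_f1 = vapply(subsets, `[[`, 0, "score"))
  data.table::fwrite(meta, file.path(dir, "essential_points.csv"))
  invisible(paths)
}

#' Write a consensus table (CSV gene counts + JSON upset cells)
#' @param cons a `consensus_table`.
#' @param csv_path path for the per-gene CSV.
#' @param json_path path for the upset-cell JSON.
#' @return `csv_path`, invisibly.
#' @export
write_consensus <- function(cons, csv_path, json_path) {
  stopifnot(inherits(cons, "consensus_table"))
  data.table::fwrite(cons$genes, csv_path)
  jsonlite::write_json(cons$upset, json_path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' Write a rule set (long CSV: one predicate per row, plus JSON)
#' @param rules a `rule_set`.
#' @param csv_path path for the predicate CSV.
#' @param json_path optional path for the nested JSON rendering.
#' @return `csv_path`, invisibly.
#' @export
write_rules <- function(rules, csv_path, json_path = NULL) {
  stopifnot(inherits(rules, "rule_set"))
  rows <- lapply(seq_along(rules), function(i) {
    r <- rules[[i]]
    p <- r$predicates
    if (!nrow(p)) {
      p <- data.frame(gene_id = NA_character_, op = NA_character_,
                      threshold = NA_real_)
    }
    data.frame(rule_id = i, p, predicted_class = r$predicted_class,
               purity = r$purity)
  })
  data.table::fwrite(do.call(rbind, rows), csv_path)
  if (!is.null(json_path)) {
    payload <- lapply(rules, function(r) list(
      predicates = r$predicates, predicted_class = r$predicted_class,
      support = as.list(r$support), purity = r$purity,
      text = format_rules(structure(list(r), class = "rule_set",
                                    gene_subset = attr(rules, "gene_subset")))
    ))
    jsonlite::write_json(payload, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
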