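#!/usr/bin/env Rscript
# Aggregate curves, essential subsets, the consensus table and rule counts
# into one JSON summary for the whole analysis.
suppressPackageStartupMessages(library(ifsmarker))

pc <- read_pipeline_config(file.path("analysis", "00_config.yaml"))
planted <- readLines(file.path("results", "planted_genes.txt"))

best_points <- lapply(pc$rankers, function(rk) {
  curve <- read_curve(file.path("results",
                                sprintf("curve_%s_%s.csv", rk,
                                        pc$selection_classifier)))
  mx <- find_max_point(curve)
  list(ranker = rk, k = mx$k, weighted_f1 = mx$score)
})

ess_meta <- data.table::fread(
  file.path("results", "essential", "essential_points.csv"),
  data.table = FALSE)
cons <- data.table::fread(file.path("results", "consensus_genes.csv"),
                          data.table = FALSE)
rule_counts_df <- data.table::fread(file.path("results", "rule_counts.csv"),
                                    data.table = FALSE)

summary <- list(
  config = unclass(pc),
  best_points = best_points,
  essential_points = ess_meta,
  consensus = list(
    n_genes = nrow(cons),
    core_genes = cons$gene_id[cons$count == length(pc$rankers)],
    planted_recovered = sum(cons$gene_id %in% planted)
  ),
  rule_counts = rule_counts_df
)
jsonlite::write_json(summary, file.path("results", "report.json"),
                     auto_unbox = TRUE, digits = NA, dataframe = "rows")
message("consensus covers ", summary$consensus$planted_recovered, "/",
        length(planted), " planted markers; report at results/report.json")
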