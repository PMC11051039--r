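#!/usr/bin/env Rscript
# Derive quantitative classification rules: for each ranker's essential
# subset, SMOTE-balance the full matrix restricted to those genes, fit one
# decision tree, and render every root-to-leaf path as a threshold rule;
# tally rules per predicted class.
suppressPackageStartupMessages(library(ifsmarker))

pc <- read_pipeline_config(file.path("analysis", "00_config.yaml"))
m <- read_matrix(file.path("results", "matrix.mtx"), format = "mtx",
                 class_names = c("active", "former", "never"))
planted <- readLines(file.path("results", "planted_genes.txt"))

count_rows <- list()
for (rk in pc$rankers) {
  genes <- data.table::fread(
    file.path("results", "essential", paste0("essential_", rk, ".csv")),
    data.table = FALSE)$gene_id
  rules <- extract_rules(m, genes, smote_k = pc$smote_k, seed = pc$seed)
  write_rules(rules, file.path("results", paste0("rules_", rk, ".csv")),
              file.path("results", paste0("rules_", rk, ".json")))
  counts <- rule_counts(rules)
  preds <- do.call(rbind, lapply(rules, `[[`, "predicates"))
  message(sprintf("%-10s %3d rules (%s); %.0f%% of predicates on planted markers",
                  rk, length(rules),
                  paste(names(counts), counts, sep = "=", collapse = " "),
                  100 * mean(preds$gene_id %in% planted)))
  count_rows[[rk]] <- data.frame(ranker = rk, t(counts), check.names = FALSE)
}
data.table::fwrite(do.call(rbind, count_rows),
                   file.path("results", "rule_counts.csv"))
message("wrote results/rules_<ranker>.csv/.json and rule_counts.csv")
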