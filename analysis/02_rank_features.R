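#!/usr/bin/env Rscript
# Rank every gene with each of the eight importance criteria and record how
# many planted markers land in each ranker's top 30 — the parameter-recovery
# view of ranking quality.
suppressPackageStartupMessages(library(ifsmarker))

pc <- read_pipeline_config(file.path("analysis", "00_config.yaml"))
m <- read_matrix(file.path("results", "matrix.mtx"), format = "mtx",
                 class_names = c("active", "former", "never"))
planted <- readLines(file.path("results", "planted_genes.txt"))

for (rk in pc$rankers) {
  rl <- rank_features(m, rk, seed = pc$seed)
  write_ranked_list(rl, file.path("results", paste0("features_", rk, ".csv")))
  hits <- sum(planted %in% top_prefix(rl, 30))
  message(sprintf("%-10s %2d/%d planted markers in top 30", rk, hits,
                  length(planted)))
}
message("wrote results/features_<ranker>.csv")
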