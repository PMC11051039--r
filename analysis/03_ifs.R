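#!/usr/bin/env Rscript
# Incremental feature selection: sweep nested prefixes of every ranked list
# (sizes 5, 10, ..., top_n) under SMOTE-balanced stratified 10-fold CV with
# the DT and RF classifiers, writing one IFS curve per (list, classifier).
suppressPackageStartupMessages(library(ifsmarker))

pc <- read_pipeline_config(file.path("analysis", "00_config.yaml"))
m <- read_matrix(file.path("results", "matrix.mtx"), format = "mtx",
                 class_names = c("active", "former", "never"))

for (rk in pc$rankers) {
  rl <- read_ranked_list(file.path("results", paste0("features_", rk, ".csv")),
                         ranker_name = rk)
  for (cls in pc$classifiers) {
    curve <- run_ifs(m, rl, cls, pc)
    write_curve(curve, file.path("results",
                                 sprintf("curve_%s_%s.csv", rk, cls)))
    message(sprintf("%-10s %s: max weighted F1 %.4f at k=%d", rk, cls,
                    max(curve$weighted_f1),
                    curve$k[which.max(curve$weighted_f1)]))
  }
}
message("wrote results/curve_<ranker>_<classifier>.csv")
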