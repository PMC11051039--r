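#!/usr/bin/env Rscript
# Extract essential feature subsets from the RF IFS curves (maximum point,
# or the earlier "relatively high" point when the maximum needs at least
# relative_k_threshold features) and intersect them across rankers into the
# consensus/upset tables.
suppressPackageStartupMessages(library(ifsmarker))

pc <- read_pipeline_config(file.path("analysis", "00_config.yaml"))
curves <- lapply(pc$rankers, function(rk) {
  read_curve(file.path("results",
                       sprintf("curve_%s_%s.csv", rk, pc$selection_classifier)))
})

ess <- essential_subsets(curves, pc)
names(ess) <- pc$rankers
for (rk in pc$rankers) print(ess[[rk]])
write_subsets(ess, file.path("results", "essential"))

cons <- consensus(ess)
print(cons)
write_consensus(cons, file.path("results", "consensus_genes.csv"),
                file.path("results", "consensus_upset.json"))
core <- cons$genes[cons$genes$count == length(ess), "gene_id"]
message("genes selected by all ", length(ess), " lists: ", length(core))
message("wrote results/essential/, consensus_genes.csv, consensus_upset.json")
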