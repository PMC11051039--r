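# Shared synthetic fixtures, built in code at test time.

# small imbalanced 3-class matrix with 6 planted markers
small_planted_fixture <- function(seed = 7, dropout = 0.3) {
  cfg <- simulation_config(
    n_cells_per_class = c(60, 70, 170), n_genes = 120,
    planted_genes = default_planted_genes(120, 3, n_markers = 6, shift = 3),
    dropout_rate = dropout, seed = seed)
  list(config = cfg, matrix = generate_dataset(cfg))
}

# 300 x 200 fixture used for IFS-grid checks
grid_fixture <- function(seed = 5) {
  cfg <- simulation_config(
    n_cells_per_class = c(45, 50, 205), n_genes = 200,
    planted_genes = default_planted_genes(200, 3, n_markers = 9, shift = 3),
    dropout_rate = 0.3, seed = seed)
  list(config = cfg, matrix = generate_dataset(cfg))
}

# random label pair on a fixed class set
random_label_pair <- function(n, classes = c("a", "b", "c")) {
  list(true = sample(classes, n, replace = TRUE),
       pred = sample(classes, n, replace = TRUE))
}
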