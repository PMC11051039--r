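test_that("generated matrices honor the configured shape and labels", {
  cfg <- simulation_config(n_cells_per_class = c(100, 100, 100), n_genes = 50,
                           planted_genes = list(), dropout_rate = 0, seed = 3)
  m <- generate_dataset(cfg)
  expect_equal(dim(m), c(300L, 50L))
  expect_equal(as.integer(table(factor(m$labels, cfg$class_names))),
               c(100L, 100L, 100L))
  expect_equal(length(unique(m$gene_ids)), 50L)
  expect_true(all(m$values >= 0))
})

test_that("planted class shifts are detectable and recoverable", {
  cfg <- simulation_config(
    n_cells_per_class = c(100, 100, 100), n_genes = 40,
    planted_genes = list(list(gene = 7L, shift = c(0, 0, 3))),
    baseline_mean = 5, noise_sd = 1, dropout_rate = 0, seed = 11)
  m <- generate_dataset(cfg)
  g <- m$values[, 7]
  in3 <- m$labels == cfg$class_names[3]
  # Welch t between the shifted class and the rest rejects at alpha = 0.001
  expect_lt(stats::t.test(g[in3], g[!in3])$p.value, 0.001)
  # class-conditional means recover the configured shift within 3 sd / sqrt(n)
  expect_lt(abs(mean(g[in3]) - mean(g[!in3]) - 3), 3 * 1 / sqrt(100))
})

test_that("dropout zeroes entries at the configured rate", {
  cfg <- simulation_config(n_cells_per_class = c(150, 150), n_genes = 2000,
                           planted_genes = list(), class_names = c("x", "y"),
                           baseline_mean = 5, dropout_rate = 0.5, seed = 2)
  m <- generate_dataset(cfg)
  expect_lt(abs(mean(m$values == 0) - 0.5), 0.02)
})

test_that("generation is bit-reproducible from the config seed", {
  cfg <- simulation_config(n_cells_per_class = c(40, 60), n_genes = 30,
                           planted_genes = list(list(gene = 1L, shift = c(2, 0))),
                           class_names = c("x", "y"), seed = 123)
  expect_identical(generate_dataset(cfg)$values, generate_dataset(cfg)$values)
  cfg2 <- simulation_config(n_cells_per_class = c(40, 60), n_genes = 30,
                            planted_genes = list(list(gene = 1L, shift = c(2, 0))),
                            class_names = c("x", "y"), seed = 124)
  expect_false(identical(generate_dataset(cfg)$values,
                         generate_dataset(cfg2)$values))
})

test_that("invalid configs fail with the offending field named", {
  expect_error(simulation_config(n_cells_per_class = c(10, 10), n_genes = 5,
                                 class_names = c("x", "y"), dropout_rate = 1),
               "dropout_rate")
  expect_error(simulation_config(n_cells_per_class = c(10, 10), n_genes = 5,
                                 class_names = c("x", "y"), noise_sd = 0),
               "noise_sd")
  expect_error(simulation_config(
    n_cells_per_class = c(10, 10), n_genes = 5, class_names = c("x", "y"),
    planted_genes = list(list(gene = 9L, shift = c(1, 0)))),
    "planted_genes")
  expect_error(simulation_config(
    n_cells_per_class = c(10, 10), n_genes = 5, class_names = c("x", "y"),
    planted_genes = list(list(gene = 2L, shift = c(1, 1)))),
    "unequal class means")
})

test_that("imbalance presets reproduce the cohort counts and preserve totals", {
  endo <- imbalance_preset("endothelial", total = 43539)
  expect_equal(endo$n_cells_per_class, c(6521L, 7189L, 29829L))
  expect_equal(endo$class_names, c("active", "former", "never"))

  stromal <- imbalance_preset("stromal", total = 16031)
  expect_equal(stromal$n_cells_per_class, c(3415L, 2342L, 10274L))

  small <- imbalance_preset("endothelial", total = 300)
  expect_equal(sum(small$n_cells_per_class), 300L)
  exact <- c(6521, 7189, 29829) / 43539 * 300
  expect_true(all(abs(small$n_cells_per_class - exact) <= 1))

  expect_error(imbalance_preset("neuronal"), "endothelial")
})

test_that("with no planted genes, no gene keeps a stable top rank across seeds", {
  mk <- function(seed) {
    cfg <- simulation_config(n_cells_per_class = c(60, 60, 80), n_genes = 250,
                             planted_genes = list(), dropout_rate = 0.3,
                             seed = seed)
    rank_features(generate_dataset(cfg), "RF", seed = 1)
  }
  a <- mk(1); b <- mk(2)
  sa <- a$score[match(sort(a$gene_id), a$gene_id)]
  sb <- b$score[match(sort(b$gene_id), b$gene_id)]
  rho <- suppressWarnings(stats::cor(sa, sb, method = "spearman"))
  expect_lt(abs(rho), 0.2)
})
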