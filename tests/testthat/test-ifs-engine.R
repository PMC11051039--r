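test_that("subset-size grids follow the step/append/clamp rules", {
  expect_equal(build_subset_sizes(200, 5), seq(5L, 200L, 5L))
  expect_length(build_subset_sizes(200, 5), 40L)
  expect_equal(build_subset_sizes(3, 5), 3L)
  expect_equal(build_subset_sizes(7, 5), c(5L, 7L))
  expect_equal(build_subset_sizes(20, 5), c(5L, 10L, 15L, 20L))
  expect_error(build_subset_sizes(0, 5), "positive")
  expect_error(build_subset_sizes(10, 0), "positive")
})

test_that("evaluate_subset pools one prediction per sample and is deterministic", {
  fx <- small_planted_fixture()
  genes <- fx$matrix$gene_ids[planted_gene_indices(fx$config)]
  rec <- evaluate_subset(fx$matrix, genes, "DT", folds = 5, seed = 42)
  expect_length(rec$pooled_pred, nrow(fx$matrix$values))
  expect_true(all(rec$pooled_pred %in% fx$matrix$class_names))
  rec2 <- evaluate_subset(fx$matrix, genes, "DT", folds = 5, seed = 42)
  expect_identical(rec$report, rec2$report)
  expect_identical(rec$pooled_pred, rec2$pooled_pred)

  expect_error(evaluate_subset(fx$matrix, c(genes, "ENSG_NOT_THERE"), "DT"),
               "absent")
  expect_error(evaluate_subset(fx$matrix, genes, "DT", folds = 1), ">= 2")
})

test_that("stratification errors when a class cannot reach every fold", {
  withr::with_seed(10, {
    X <- matrix(rnorm(40 * 5), nrow = 40)
    y <- c(rep("a", 30), rep("b", 7), rep("c", 3))
    m <- labeled_matrix(X, paste0("g", 1:5), y)
  })
  expect_error(evaluate_subset(m, paste0("g", 1:3), "DT", folds = 5),
               "fewer folds")
})

test_that("a subset of planted markers classifies well and pure noise does not", {
  fx <- small_planted_fixture()
  planted <- fx$matrix$gene_ids[planted_gene_indices(fx$config)]
  rec <- evaluate_subset(fx$matrix, planted, "RF", folds = 5, seed = 6)
  expect_gt(rec$report$weighted_f1, 0.9)

  noise_genes <- setdiff(fx$matrix$gene_ids, planted)[1:6]
  rec_noise <- evaluate_subset(fx$matrix, noise_genes, "RF", folds = 5,
                               seed = 6)
  # chance band: the empirical null from label-permuted evaluations
  null_scores <- vapply(1:10, function(i) {
    m2 <- fx$matrix
    withr::with_seed(100 + i, m2$labels <- sample(m2$labels))
    evaluate_subset(m2, noise_genes, "RF", folds = 5, seed = 6)$report$weighted_f1
  }, numeric(1))
  expect_lt(rec_noise$report$weighted_f1,
            mean(null_scores) + 3 * stats::sd(null_scores) + 1e-8)
})

test_that("run_ifs produces one record per grid size over nested prefixes", {
  fx <- small_planted_fixture()
  rl <- rank_features(fx$matrix, "RF", seed = 3)
  cfg <- pipeline_config(top_n = 20, step = 5, cv_folds = 5, seed = 3)
  curve <- run_ifs(fx$matrix, rl, "DT", cfg)
  expect_equal(curve$k, c(5L, 10L, 15L, 20L))
  expect_identical(attr(curve, "gene_ids"), top_prefix(rl, 20))
  expect_true(all(curve$weighted_f1 >= 0 & curve$weighted_f1 <= 1))
  expect_true(all(paste0("f1_", fx$matrix$class_names) %in% names(curve)))
})

test_that("evaluation folds never contain synthetic samples", {
  # the training data handed to SMOTE excludes the evaluation fold, so fold
  # predictions must be reproducible from original rows only; verify by
  # checking that the pooled prediction of each sample is produced when that
  # sample's fold is held out (prediction count equals n exactly once each)
  fx <- small_planted_fixture()
  genes <- fx$matrix$gene_ids[planted_gene_indices(fx$config)]
  rec <- evaluate_subset(fx$matrix, genes, "DT", folds = 4, seed = 2)
  expect_length(rec$pooled_pred, nrow(fx$matrix$values))
  expect_false(any(rec$pooled_pred == ""))
})

test_that("DT does not outperform RF on the planted fixture curve", {
  fx <- small_planted_fixture()
  rl <- rank_features(fx$matrix, "RF", seed = 3)
  cfg <- pipeline_config(top_n = 15, step = 5, cv_folds = 5, seed = 3)
  dt <- run_ifs(fx$matrix, rl, "DT", cfg)
  rf <- run_ifs(fx$matrix, rl, "RF", cfg)
  # fixture-specific assertion at a fixed seed, not a theorem
  expect_true(all(dt$weighted_f1 <= rf$weighted_f1 + 1e-8))
})
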