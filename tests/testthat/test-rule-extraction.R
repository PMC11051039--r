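sep_gene_matrix <- function() {
  # one perfectly separating gene, balanced classes
  withr::with_seed(41, {
    n <- 80
    y <- rep(c("a", "b"), each = n / 2)
    x <- ifelse(y == "a", stats::rnorm(n, 0, 0.1), stats::rnorm(n, 6, 0.1))
    labeled_matrix(matrix(x, ncol = 1), "gene_sep", y)
  })
}

test_that("a depth-1 tree yields exactly two pure rules", {
  m <- sep_gene_matrix()
  rules <- extract_rules(m, "gene_sep", seed = 2, max_depth = 1)
  expect_length(rules, 2L)
  expect_setequal(vapply(rules, `[[`, "", "predicted_class"), c("a", "b"))
  expect_equal(vapply(rules, `[[`, 0, "purity"), c(1, 1))
  expect_equal(nrow(rules[[1]]$predicates), 1L)
})

test_that("rules partition feature space and are faithful to the tree", {
  fx <- small_planted_fixture()
  genes <- fx$matrix$gene_ids[planted_gene_indices(fx$config)]
  rules <- extract_rules(fx$matrix, genes, seed = 5)
  # every training sample matches exactly one rule (apply_rules errors
  # otherwise) ...
  train <- fx$matrix$values[, match(genes, fx$matrix$gene_ids)]
  res_train <- apply_rules(rules, train)
  expect_length(res_train$class, nrow(train))
  # ... as does any random input vector
  withr::with_seed(9, {
    rand <- matrix(stats::runif(10000 * length(genes), -2, 10),
                   ncol = length(genes))
  })
  res_rand <- apply_rules(rules, rand)
  expect_length(res_rand$class, 10000L)
  expect_true(all(res_rand$class %in% fx$matrix$class_names))
})

test_that("redundant same-side predicates merge into the tightest bound", {
  preds <- data.frame(gene_id = c("g", "g", "g"), op = c("<=", "<=", ">"),
                      threshold = c(5, 3, 1), stringsAsFactors = FALSE)
  merged <- ifsmarker:::merge_predicates(preds)
  expect_equal(nrow(merged), 2L)
  expect_equal(merged$threshold[merged$op == "<="], 3)
  expect_equal(merged$threshold[merged$op == ">"], 1)

  # merging never changes which rule a sample matches: deep tree on few genes
  fx <- small_planted_fixture()
  genes <- fx$matrix$gene_ids[planted_gene_indices(fx$config)][1:3]
  rules <- extract_rules(fx$matrix, genes, seed = 5, minsplit = 5)
  vals <- fx$matrix$values[, match(genes, fx$matrix$gene_ids)]
  got <- apply_rules(rules, vals)  # errors unless still a partition
  expect_length(got$class, nrow(vals))
  # predicted class of the matched rule equals the majority class of its leaf
  for (r in rules) {
    expect_equal(r$predicted_class,
                 names(which.max(r$support))[1])
    expect_equal(r$purity, max(r$support) / sum(r$support))
  }
})

test_that("rule counts tally leaves per class and flag the expected pattern", {
  m <- sep_gene_matrix()
  rules <- extract_rules(m, "gene_sep", seed = 2, max_depth = 1)
  expect_equal(unname(rule_counts(rules)), c(1L, 1L))

  fx <- small_planted_fixture()
  genes <- fx$matrix$gene_ids[planted_gene_indices(fx$config)]
  rules2 <- extract_rules(fx$matrix, genes, seed = 5)
  counts <- rule_counts(rules2)
  expect_equal(sum(counts), length(rules2))
  # the majority class should not have the fewest rules on this fixture
  expect_false(names(which.min(counts))[1] == "never")
})

test_that("rule text renders thresholds and conjunctions", {
  m <- sep_gene_matrix()
  rules <- extract_rules(m, "gene_sep", seed = 2, max_depth = 1)
  txt <- format_rules(rules)
  expect_match(txt[1], "^IF gene_sep (<=|>) ")
  expect_match(txt[1], "THEN (a|b)")
})
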