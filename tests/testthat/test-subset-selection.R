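test_that("the maximum point takes the smallest k achieving the maximum", {
  expect_equal(find_max_point(ifs_curve(c(5, 10, 15), c(0.80, 0.90, 0.90)))$k, 10)
  expect_equal(find_max_point(ifs_curve(c(5, 10, 15), c(0.1, 0.2, 0.3)))$k, 15)
})

test_that("the published endothelial example curve selects k=50 at delta 0.015", {
  # curve embedding the reported values: maximum 0.917 at k=105 and the
  # relatively high value 0.903 at k=50
  k <- seq(5, 200, by = 5)
  f1 <- 0.85 + 0.0005 * k
  f1[k == 105] <- 0.917
  f1[k == 50] <- 0.903
  f1[k > 105] <- 0.90
  f1[k > 50 & k < 105] <- 0.901
  f1[k < 50] <- 0.87
  curve <- ifs_curve(k, f1, ranker = "ExtraTrees")
  mx <- find_max_point(curve)
  expect_equal(mx$k, 105)
  expect_equal(mx$score, 0.917)
  rel <- find_relative_high_point(curve, delta = 0.015, k_threshold = 100)
  expect_equal(rel$k, 50)
  expect_equal(rel$score, 0.903)
  expect_equal(rel$point_kind, "relative_high")
})

test_that("no relative point is returned below the k threshold or at delta 0", {
  curve <- ifs_curve(c(50, 70, 90), c(0.80, 0.95, 0.94))
  expect_equal(find_max_point(curve)$k, 70)
  expect_null(find_relative_high_point(curve, delta = 0.015, k_threshold = 100))

  # at delta 0 only an exact earlier tie could qualify, but the parsimony
  # tie-break already makes the earliest tie the maximum point itself, so no
  # strictly smaller prefix can remain
  curve2 <- ifs_curve(c(50, 100, 150), c(0.90, 0.93, 0.93))
  expect_equal(find_max_point(curve2)$k, 100)
  expect_null(find_relative_high_point(curve2, delta = 0))
  curve3 <- ifs_curve(c(100, 120, 150), c(0.93, 0.93, 0.90))
  expect_equal(find_max_point(curve3)$k, 100)
  expect_null(find_relative_high_point(curve3, delta = 0))
})

test_that("essential subsets replace large maxima by their relative points", {
  mk_curve <- function(kmax, krel = NULL, ranker = "RF") {
    k <- seq(5, 150, by = 5)
    f1 <- rep(0.8, length(k))
    f1[k == kmax] <- 0.95
    if (!is.null(krel)) f1[k == krel] <- 0.94
    ifs_curve(k, f1, ranker = ranker, gene_ids = sprintf("g%03d", 1:150))
  }
  cfg <- pipeline_config(relative_delta = 0.015, relative_k_threshold = 100)
  subsets <- essential_subsets(
    list(mk_curve(45, ranker = "A"), mk_curve(120, krel = 45, ranker = "B")),
    cfg)
  expect_equal(subsets[[1]]$point_kind, "max")
  expect_equal(subsets[[1]]$k, 45)
  expect_equal(subsets[[2]]$point_kind, "relative_high")
  expect_equal(subsets[[2]]$k, 45)
  expect_length(subsets[[2]]$gene_ids, 45)
  expect_identical(subsets[[2]]$gene_ids, sprintf("g%03d", 1:45))
})

make_subset <- function(ranker, genes) {
  structure(list(ranker_name = ranker, classifier_name = "RF",
                 point_kind = "max", k = length(genes), score = 0.9,
                 gene_ids = genes), class = "essential_subset")
}

test_that("consensus counts and upset cells match hand enumeration", {
  subs <- list(make_subset("r1", c("A", "B", "C")),
               make_subset("r2", c("B", "C", "D")),
               make_subset("r3", c("C")))
  cons <- consensus(subs)
  counts <- stats::setNames(cons$genes$count, cons$genes$gene_id)
  expect_equal(counts, c(A = 1L, B = 2L, C = 3L, D = 1L))
  up <- stats::setNames(cons$upset$size, cons$upset$combination)
  expect_equal(up[["r1"]], 1L)          # A
  expect_equal(up[["r1/r2"]], 1L)       # B
  expect_equal(up[["r1/r2/r3"]], 1L)    # C
  expect_equal(up[["r2"]], 1L)          # D
  expect_equal(sum(cons$upset$size), 4L)
})

test_that("degenerate consensus families behave as identities", {
  same <- lapply(paste0("r", 1:8), make_subset, genes = c("X", "Y"))
  cons <- consensus(same)
  expect_true(all(cons$genes$count == 8L))
  expect_equal(nrow(cons$upset), 1L)

  disjoint <- list(make_subset("r1", "A"), make_subset("r2", "B"))
  expect_true(all(consensus(disjoint)$genes$count == 1L))

  single <- consensus(list(make_subset("r1", c("A", "B"))))
  expect_equal(single$genes$count, c(1L, 1L))
})

test_that("randomized consensus families match brute-force enumeration", {
  withr::with_seed(77, {
    for (rep in 1:5) {
      universe <- sprintf("G%02d", 1:40)
      subs <- lapply(paste0("r", 1:8), function(r) {
        make_subset(r, sample(universe, sample(5:15, 1)))
      })
      cons <- consensus(subs)
      # brute force over all 255 nonempty ranker combinations
      membership <- vapply(subs, function(s) universe %in% s$gene_ids,
                           logical(40))
      seen <- 0L
      for (mask in 1:255) {
        in_combo <- as.logical(bitwAnd(mask, 2^(0:7)))
        cell <- sum(apply(membership, 1, function(row) all(row == in_combo)))
        combo_name <- paste(sort(paste0("r", which(in_combo))), collapse = "/")
        got <- cons$upset$size[cons$upset$combination == combo_name]
        expect_equal(if (length(got)) got else 0L, cell)
        seen <- seen + cell
      }
      expect_equal(seen, nrow(cons$genes))
      expect_equal(sum(cons$upset$size), nrow(cons$genes))
    }
  })
})
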