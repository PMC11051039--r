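test_that("confusion tabulates TP/FP/FN and class weights correctly", {
  cs <- confusion(c("a", "a", "b"), c("a", "b", "b"), c("a", "b"))
  expect_equal(cs$tp, c(1L, 1L))
  expect_equal(cs$fp, c(0L, 1L))
  expect_equal(cs$fn, c(1L, 0L))
  expect_equal(cs$weight, c(2 / 3, 1 / 3))

  perfect <- confusion(c("a", "b", "c"), c("a", "b", "c"))
  expect_true(all(perfect$fp == 0L) && all(perfect$fn == 0L))

  single <- confusion(rep("x", 4), rep("x", 4), class_names = c("x", "y"))
  expect_equal(single$weight[single$class == "x"], 1)
  expect_equal(single$weight[single$class == "y"], 0)

  expect_error(confusion(c("a", "b"), c("a")), "equal length")
  expect_error(confusion(c("a", "z"), c("a", "a"), class_names = c("a", "b")),
               "unknown label")
})

test_that("weighted F1 is the harmonic mean of weighted precision and recall", {
  classes <- c("a", "b", "c")
  true <- c("a", "a", "a", "b", "b", "c")
  pred <- c("a", "a", "b", "b", "c", "c")
  cs <- confusion(true, pred, classes)
  expect_equal(weighted_f1(cs), oracle_weighted_f1(true, pred, classes))

  # all-majority prediction, balanced binary: Pw = 0.25, Rw = 0.5, F1 = 1/3
  true2 <- c("a", "a", "b", "b")
  pred2 <- rep("a", 4)
  cs2 <- confusion(true2, pred2, c("a", "b"))
  expect_equal(weighted_f1(cs2), 1 / 3)
  # ... and differs from the classwise-averaged variant on the same input
  expect_equal(weighted_f1_classwise(cs2), 1 / 3)  # happens to agree here
  true3 <- c("a", "a", "a", "b")
  cs3 <- confusion(true3, c("a", "b", "b", "b"), c("a", "b"))
  expect_false(isTRUE(all.equal(weighted_f1(cs3), weighted_f1_classwise(cs3))))

  perfect <- confusion(c("a", "b", "b"), c("a", "b", "b"))
  expect_equal(weighted_f1(perfect), 1)
})

test_that("macro F1 and accuracy match their definitions", {
  expect_equal(macro_f1(confusion(c("a", "b"), c("a", "b"))), 1)
  expect_equal(acc(c("a", "b"), c("b", "a")), 0)
  withr::with_seed(42, {
    for (rep in 1:20) {
      pair <- random_label_pair(24)
      cs <- confusion(pair$true, pair$pred, c("a", "b", "c"))
      expect_equal(macro_f1(cs), oracle_macro_f1(pair$true, pair$pred, c("a", "b", "c")))
      expect_equal(acc(pair$true, pair$pred), oracle_acc(pair$true, pair$pred))
    }
  })
  # balanced classes: weighted classwise average equals macro
  withr::with_seed(1, {
    true <- rep(c("a", "b", "c"), each = 12)
    pred <- sample(c("a", "b", "c"), 36, replace = TRUE)
    cs <- confusion(true, pred, c("a", "b", "c"))
    expect_equal(weighted_f1_classwise(cs), macro_f1(cs))
  })
})

test_that("multiclass MCC matches the indicator-matrix and binary oracles", {
  expect_equal(mcc(c("a", "b", "c"), c("a", "b", "c")), 1)

  # binary toy table TP=45 TN=40 FP=10 FN=5
  lab <- binary_labels_from_table(45, 40, 10, 5)
  expect_equal(mcc(lab$true, lab$pred, c("neg", "pos")),
               oracle_binary_mcc(45, 40, 10, 5))

  # cyclic shift on balanced 3 classes: negative association
  true <- rep(c("a", "b", "c"), each = 10)
  shift <- c(a = "b", b = "c", c = "a")
  pred <- unname(shift[true])
  got <- mcc(true, pred, c("a", "b", "c"))
  expect_lt(got, 0)
  expect_equal(got, oracle_mcc(true, pred, c("a", "b", "c")))

  # constant prediction: degenerate, defined as 0
  expect_message(got0 <- mcc(c("a", "b"), c("a", "a")), "degenerate")
  expect_equal(got0, 0)
})

test_that("metric bounds hold on random label pairs and permutation nulls center at zero", {
  withr::with_seed(99, {
    mccs <- numeric(200)
    for (i in 1:200) {
      pair <- random_label_pair(30)
      cs <- confusion(pair$true, pair$pred, c("a", "b", "c"))
      wf <- weighted_f1(cs)
      expect_gte(wf, 0); expect_lte(wf, 1)
      m <- mcc(pair$true, pair$pred, c("a", "b", "c"))
      expect_gte(m, -1); expect_lte(m, 1)
      mccs[i] <- m
    }
    # permutation null: E[MCC] ~ 0 within Monte-Carlo error
    expect_lt(abs(mean(mccs)), 3 / sqrt(200 * 30))
  })
})

test_that("metric reports serialize to JSON with stable keys", {
  rep_ <- metric_report(c("a", "a", "b"), c("a", "b", "b"), c("a", "b"))
  parsed <- jsonlite::fromJSON(metric_report_json(rep_))
  expect_named(parsed, c("weighted_f1", "macro_f1", "acc", "mcc", "per_class"))
  expect_equal(parsed$weighted_f1, rep_$weighted_f1)
  expect_named(parsed$per_class$f1, c("a", "b"))
})
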