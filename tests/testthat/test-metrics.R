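test_that("confusion_matrix tallies truth against prediction", {
  cm <- confusion_matrix(c("a", "a", "b", "b"), c("a", "b", "b", "b"),
                         labels = c("a", "b"))
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 2L), 2,
                                   dimnames = list(truth = c("a", "b"),
                                                   predicted = c("a", "b"))))
  perfect <- confusion_matrix(rep(scinti_classes(), 4), rep(scinti_classes(), 4))
  expect_true(all(unclass(perfect)[upper.tri(perfect) | lower.tri(perfect)] == 0))
  set.seed(2)
  t5 <- sample(scinti_classes(), 50, replace = TRUE)
  p5 <- sample(scinti_classes(), 50, replace = TRUE)
  expect_equal(sum(confusion_matrix(t5, p5)), 50)  # conservation
  expect_error(confusion_matrix(c("a", "b"), c("a")), "length")
  expect_error(confusion_matrix(c("a"), c("z"), labels = "a"), "outside")
})

test_that("metric suite matches hand computations one-vs-rest", {
  # symmetric binary case: TP=8 FP=2 FN=2 TN=8
  cm <- matrix(c(8L, 2L, 2L, 8L), 2,
               dimnames = list(c("pos", "neg"), c("pos", "neg")))
  r <- classification_metrics(cm)
  pos <- r$per_class[r$per_class$class == "pos", ]
  expect_equal(pos$precision, 0.8)
  expect_equal(pos$recall, 0.8)
  expect_equal(pos$specificity, 0.8)
  expect_equal(pos$f1, 0.8)
  expect_equal(r$overall_accuracy, 0.8)

  # asymmetric case: TP=3 FP=1 FN=2 TN=4
  cm2 <- matrix(c(3L, 1L, 2L, 4L), 2,
                dimnames = list(c("pos", "neg"), c("pos", "neg")))
  r2 <- classification_metrics(cm2)
  pos2 <- r2$per_class[r2$per_class$class == "pos", ]
  expect_equal(pos2$precision, 0.75)
  expect_equal(pos2$recall, 0.6)
  expect_equal(pos2$specificity, 0.8)
  expect_equal(pos2$accuracy, 0.7)
  expect_equal(pos2$f1, 2 * 0.75 * 0.6 / (0.75 + 0.6), tolerance = 1e-9)

  # perfect three-class case: everything 1
  cmp <- diag(c(5L, 4L, 6L))
  dimnames(cmp) <- list(scinti_classes(), scinti_classes())
  rp <- classification_metrics(cmp)
  expect_true(all(rp$per_class$precision == 1))
  expect_true(all(rp$per_class$f1 == 1))
  expect_equal(rp$macro$f1, 1)
  expect_equal(rp$overall_accuracy, 1)
})

test_that("zero-denominator metrics report 0 with the degenerate flag", {
  # class never predicted and never true -> precision/recall undefined
  cm <- matrix(c(5L, 0L, 0L, 0L), 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  r <- classification_metrics(cm)
  b <- r$per_class[r$per_class$class == "b", ]
  expect_equal(b$precision, 0)
  expect_equal(b$recall, 0)
  expect_true(b$degenerate)
  expect_error(classification_metrics(matrix(0L, 2, 2)), "empty")
})

test_that("per-class F1 is the harmonic mean; macro-F1 deliberately is not", {
  cm <- matrix(c(10L, 4L, 1L, 2L, 8L, 3L, 0L, 2L, 9L), 3, byrow = TRUE,
               dimnames = list(scinti_classes(), scinti_classes()))
  r <- classification_metrics(cm)
  for (i in 1:3) {
    pc <- r$per_class[i, ]
    expect_equal(pc$f1, 2 * pc$precision * pc$recall / (pc$precision + pc$recall),
                 tolerance = 1e-12)
  }
  hm <- 2 * r$macro$precision * r$macro$recall /
    (r$macro$precision + r$macro$recall)
  expect_false(isTRUE(all.equal(r$macro$f1, hm, tolerance = 1e-6)))
})

test_that("AUC: closed cases, pair-counting equality, and reversal", {
  # perfectly separating scores
  r <- roc_auc(c(TRUE, TRUE, FALSE, FALSE), c(0.9, 0.8, 0.3, 0.1))
  expect_equal(r$macro_auc, 1)
  # identical scores: no discrimination
  r0 <- roc_auc(c(TRUE, FALSE, TRUE, FALSE), rep(0.5, 4))
  expect_equal(r0$macro_auc, 0.5)
  # 4-sample case with 3 of 4 concordant pairs
  r34 <- roc_auc(c(TRUE, TRUE, FALSE, FALSE), c(0.9, 0.4, 0.6, 0.2))
  expect_equal(r34$macro_auc, 0.75)

  set.seed(7)
  for (i in 1:25) {
    n <- sample(4:50, 1)
    pos <- runif(n) < 0.5
    if (!any(pos) || all(pos)) next
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce some ties
    got <- roc_auc(pos, scores)$macro_auc
    expect_equal(got, pair_count_auc(scores, pos), tolerance = 1e-9)
    rev <- roc_auc(pos, -scores)$macro_auc
    expect_equal(rev, 1 - got, tolerance = 1e-9)
  }
})

test_that("binary AUC agrees with the independent pROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  for (i in 1:5) {
    y <- c(rep(1, 10), rep(0, 12))
    s <- c(rnorm(10, 1), rnorm(12, 0))
    ours <- roc_auc(y == 1, s)$macro_auc
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<", levels = c(0, 1))))
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("multiclass ROC reports per-class, macro and micro views", {
  set.seed(12)
  n <- 60
  truth <- sample(scinti_classes(), n, replace = TRUE)
  scores <- matrix(runif(3 * n), n, 3,
                   dimnames = list(NULL, scinti_classes()))
  # tilt the scores toward the truth so AUC > 0.5
  for (i in seq_len(n)) {
    scores[i, truth[i]] <- scores[i, truth[i]] + 0.6
  }
  scores <- scores / rowSums(scores)
  r <- roc_auc(truth, scores)
  expect_equal(nrow(r$per_class), 3)
  expect_equal(r$macro_auc, mean(r$per_class$auc))
  expect_gt(r$macro_auc, 0.6)
  expect_true("micro" %in% r$curves$class)
  # macro AUC equals the mean of per-class pair-counting AUCs
  for (cl in scinti_classes()) {
    expect_equal(r$per_class$auc[r$per_class$class == cl],
                 pair_count_auc(scores[, cl], truth == cl), tolerance = 1e-9)
  }
  # a class with no positives is excluded with a warning
  truth2 <- truth; truth2[truth2 == "nADMet"] <- "ADMet"
  expect_warning(r2 <- roc_auc(truth2, scores), "nADMet")
  expect_equal(nrow(r2$per_class), 2)
})

test_that("merge_metastatic collapses the two metastatic classes", {
  expect_equal(merge_metastatic(c("NoMet", "ADMet", "nADMet")),
               c("NoMet", "Met", "Met"))
  expect_error(merge_metastatic("Else"), "Unknown")
})
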