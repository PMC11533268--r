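test_that("confusion counts identify the mutated class as positive", {
  expect_equal(confusionCounts(rep(c(1, 0), each = 5), rep(c(1, 0), each = 5)),
               c(TP = 5L, FP = 0L, TN = 5L, FN = 0L))
  expect_equal(confusionCounts(rep(c(1, 0), each = 5), rep(1, 10)),
               c(TP = 5L, FP = 5L, TN = 0L, FN = 0L))
  expect_equal(confusionCounts(c(1, 0, 1, 0), c(1, 1, 0, 0)),
               c(TP = 1L, FP = 1L, TN = 1L, FN = 1L))
  expect_error(confusionCounts(c(1, 0), c(1)), "length")
})

test_that("the metric panel matches independent arithmetic", {
  # hand-checked confusion table
  rep1 <- computeMetrics(c(TP = 40L, FP = 5L, TN = 45L, FN = 10L))
  m <- metricValues(rep1)
  expect_equal(unname(m["sensitivity"]), 0.80)
  expect_equal(unname(m["specificity"]), 0.90)
  expect_equal(unname(m["accuracy"]), 0.85)
  expect_equal(unname(m["precision"]), 8 / 9)
  expect_equal(unname(m["f1"]), 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8))
  expect_equal(unname(m["mcc"]),
               (40 * 45 - 5 * 10) / sqrt(45 * 50 * 50 * 55))
  # observed/chance agreement: P_o = 0.8, P_e = 0.5 gives kappa 0.6
  rep2 <- computeMetrics(c(TP = 40L, FP = 10L, TN = 40L, FN = 10L))
  expect_equal(unname(rep2@agreement), c(0.8, 0.5))
  expect_equal(unname(metricValues(rep2)["cohens_kappa"]), 0.6)
  # perfect classifier
  perf <- metricValues(computeMetrics(c(TP = 5L, FP = 0L, TN = 5L, FN = 0L)))
  expect_equal(unname(perf[c("accuracy", "mcc", "cohens_kappa", "f1")]),
               rep(1, 4))

  set.seed(31)
  for (rep in 1:100) {
    cc <- as.integer(rpois(4, 12) + 1)
    names(cc) <- c("TP", "FP", "TN", "FN")
    got <- metricValues(computeMetrics(cc))
    want <- bruteMetrics(cc["TP"], cc["FP"], cc["TN"], cc["FN"])
    expect_equal(unname(got["accuracy"]), unname(want$accuracy))
    expect_equal(unname(got["precision"]), unname(want$precision))
    expect_equal(unname(got["recall"]), unname(want$recall))
    expect_equal(unname(got["sensitivity"]), unname(want$recall))
    expect_equal(unname(got["specificity"]), unname(want$specificity))
    expect_equal(unname(got["f1"]), unname(want$f1))
    expect_equal(unname(got["mcc"]), unname(want$mcc))
    expect_equal(unname(got["cohens_kappa"]), unname(want$kappa))
  }
})

test_that("degenerate confusion tables flag metrics instead of erroring", {
  rep0 <- computeMetrics(c(TP = 0L, FP = 0L, TN = 10L, FN = 0L))
  expect_true("precision" %in% rep0@flags)
  expect_true(is.nan(metricValues(rep0)["precision"]))
  expect_true(is.nan(metricValues(rep0)["cohens_kappa"]))  # P_e == 1
  expect_equal(unname(metricValues(rep0)["accuracy"]), 1)
})

test_that("AUC equals the exhaustive concordant-pair count", {
  expect_equal(rocPoints(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(rocPoints(rep(0.5, 8), rep(c(1, 0), 4))$auc, 0.5)
  expect_equal(rocPoints(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))$auc, 0.75)
  expect_warning(rocPoints(runif(5), rep(1, 5)), "one class")
  set.seed(32)
  for (rep in 1:100) {
    n <- sample(4:50, 1)
    truth <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    prob <- round(runif(n), sample(1:3, 1))   # coarse grids force ties
    expect_equal(rocPoints(prob, truth)$auc, bruteAuc(prob, truth))
  }
})

test_that("AUC agrees with an external reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  for (rep in 1:10) {
    truth <- sample(0:1, 40, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(truth)) < 2) next
    prob <- round(runif(40), 2)
    ref <- as.numeric(pROC::auc(pROC::roc(truth, prob, quiet = TRUE,
                                          direction = "<")))
    expect_equal(rocPoints(prob, truth)$auc, ref)
  }
})

test_that("ROC curves start at (0,0), end at (1,1) and are nondecreasing", {
  set.seed(34)
  for (rep in 1:20) {
    truth <- c(0, 1, sample(0:1, 30, replace = TRUE))
    prob <- round(runif(32), 2)
    roc <- rocPoints(prob, truth)$roc
    expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
    expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
    expect_true(all(diff(roc$fpr) >= 0))
    expect_true(all(diff(roc$tpr) >= 0))
  }
})

test_that("split plans satisfy disjointness, coverage and stratification", {
  for (seed in c(1L, 7L, 101L)) {
    y <- rep(c(0, 1), 50)
    ist <- makeSplitPlan(y, "ist", seed = seed)
    expect_equal(sum(ist$test), 20L)
    expect_equal(sum(ist$test & y == 1), 10L)
    expect_equal(sum(ist$test & y == 0), 10L)
    # same seed reproduces the identical split
    expect_identical(ist$test, makeSplitPlan(y, "ist", seed = seed)$test)

    kf <- makeSplitPlan(y, "kfold", seed = seed)
    sizes <- table(kf$fold)
    expect_equal(length(sizes), 10L)
    expect_lte(diff(range(sizes)), 1)
    expect_equal(sort(unique(kf$fold)), 1:10)
    expect_equal(length(kf$fold), 100L)
    perClass <- table(kf$fold, y)
    expect_lte(diff(range(perClass[, "1"])), 1)
  }
  # unbalanced labels still stratify
  y2 <- rep(c(0, 1), c(30, 70))
  ist2 <- makeSplitPlan(y2, "ist", seed = 3L)
  expect_equal(sum(ist2$test & y2 == 0), 6L)
  expect_equal(sum(ist2$test & y2 == 1), 14L)
  expect_error(makeSplitPlan(rep(0:1, 2), "kfold"), "at least")
  sct <- makeSplitPlan(y2, "sct")
  expect_null(sct$test)
  expect_equal(sct$protocol, "sct")
})

test_that("standardization maps the training range to [0,1] without leaking", {
  set.seed(35)
  Xtr <- matrix(runif(60, -5, 5), 12, 5)
  Xtr[, 3] <- 2  # constant feature
  std <- fitStandardizer(Xtr)
  S <- applyStandardizer(std, Xtr)
  expect_equal(unname(apply(S[, -3], 2, min)), rep(0, 4))
  expect_equal(unname(apply(S[, -3], 2, max)), rep(1, 4))
  expect_equal(S[, 3], rep(0, 12))
  # test-set values transform with the training parameters only
  Xte <- matrix(10, 2, 5)
  expect_true(any(applyStandardizer(std, Xte) > 1))
})

test_that("evaluation protocols run end to end on a tiny planted-signal corpus", {
  cfg <- syntheticConfig(nGenes = 4L, lengthRange = c(40L, 60L),
                         nMutations = 20L, effectSize = 1, seed = 13L)
  se <- featurize(generateLabeledCorpus(cfg))
  configs <- tinyConfigs(522L, epochs = 25L, seed = 2L)

  sct <- runSCT(se, configs, seed = 5L)
  expect_s4_class(sct, "MetricsReport")
  expect_equal(sct@protocol, "sct")
  expect_equal(sum(confusionOf(sct)), 40L)

  ist <- runIST(se, configs, seed = 5L)
  expect_equal(ist@protocol, "ist")
  expect_equal(sum(confusionOf(ist)), 8L)   # 20% of 40

  kf <- run10FCV(se, tinyConfigs(522L, epochs = 8L, seed = 2L), seed = 5L)
  expect_equal(kf$pooled@protocol, "kfold")
  expect_equal(sum(confusionOf(kf$pooled)), 40L)  # pooled confusion covers all
  expect_length(kf$perFold, 10L)
  foldTotals <- vapply(kf$perFold, function(r) sum(confusionOf(r)), integer(1))
  expect_equal(sum(foldTotals), 40L)
  expect_lte(diff(range(foldTotals)), 1)
})
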