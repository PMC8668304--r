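test_that("70/10/20 splits reproduce the reference partition counts", {
  cases <- list(c(1425, 998, 142, 285),
                c(1675, 1173, 167, 335),
                c(2470, 1729, 247, 494),
                c(10, 7, 1, 2))
  for (cs in cases) {
    s <- splitDataset(cs[1], seed = 3)
    expect_identical(length(s@trainIdx), as.integer(cs[2]))
    expect_identical(length(s@valIdx), as.integer(cs[3]))
    expect_identical(length(s@testIdx), as.integer(cs[4]))
    expect_identical(sort(c(s@trainIdx, s@valIdx, s@testIdx)),
                     seq_len(cs[1]))
  }
  expect_error(splitDataset(9), ">= 10")
  # counts deterministic in n, membership varies with seed
  a <- splitDataset(100, seed = 1)
  b <- splitDataset(100, seed = 2)
  expect_false(identical(a@trainIdx, b@trainIdx))
  expect_identical(length(a@trainIdx), length(b@trainIdx))
})

test_that("binary confusion counts the four cells correctly", {
  cm <- binaryConfusion(c("P", "P", "N", "N"), c("P", "N", "P", "N"),
                        positive = "P")
  expect_equal(c(cm@TP, cm@FN, cm@FP, cm@TN), c(1, 1, 1, 1))
  # perfect prediction has no off-diagonal mass
  y <- sample(c("tumor", "normal"), 30, TRUE)
  cmP <- binaryConfusion(y, y, positive = "tumor")
  expect_equal(cmP@FP + cmP@FN, 0)
  # swapping the positive class swaps TP<->TN and FP<->FN
  a <- binaryConfusion(c("P", "P", "N"), c("P", "N", "P"), positive = "P")
  b <- binaryConfusion(c("P", "P", "N"), c("P", "N", "P"), positive = "N")
  expect_equal(c(a@TP, a@FN, a@FP, a@TN), c(b@TN, b@FP, b@FN, b@TP))
  expect_error(binaryConfusion(c("a", "b"), c("c", "d")), "2-value")
  expect_error(binaryConfusion(c("a", "b"), "a"), "equal length")
})

test_that("metrics follow their defining formulas as percentages", {
  # 275 of 285 test images correct -> 96.49% accuracy (and the 2019/2020
  # analogues)
  for (cs in list(c(275, 285, 96.49), c(326, 335, 97.31),
                  c(488, 494, 98.79))) {
    yTrue <- rep(c("tumor", "normal"), length.out = cs[2])
    yPred <- yTrue
    yPred[seq_len(cs[2] - cs[1])] <-
      ifelse(yTrue[seq_len(cs[2] - cs[1])] == "tumor", "normal", "tumor")
    m <- computeMetrics(binaryConfusion(yTrue, yPred, positive = "tumor"))
    expect_equal(round(m@accuracy, 2), cs[3])
  }
  # uniform matrix: everything 50%
  u <- computeMetrics(new("ConfusionMatrix", TP = 1, FP = 1, FN = 1, TN = 1,
                          positive = "x"))
  expect_equal(as.vector(u), c(accuracy = 50, sensitivity = 50,
                               specificity = 50, precision = 50, dice = 50))
  expect_error(computeMetrics(new("ConfusionMatrix", TP = 0, FP = 0, FN = 0,
                                  TN = 0, positive = "x")), "degenerate")
  # undefined metrics surface as NaN with a warning, not as 0 or 100
  noPos <- new("ConfusionMatrix", TP = 0, FP = 0, FN = 5, TN = 5,
               positive = "x")
  expect_warning(m2 <- computeMetrics(noPos), "precision")
  expect_true(is.nan(m2@precision))
})

test_that("dice equals the harmonic mean of precision and recall", {
  expect_equal(round(diceFromPrecisionRecall(96.74, 97.80), 2), 97.27)
  # algebraic identity: harmonic-mean form equals 2TP/(2TP+FP+FN)
  set.seed(31)
  for (rep in 1:20) {
    cm <- new("ConfusionMatrix", TP = sample(1:50, 1), FP = sample(0:20, 1),
              FN = sample(0:20, 1), TN = sample(0:50, 1), positive = "x")
    m <- suppressWarnings(computeMetrics(cm))
    expect_equal(m@dice, 100 * 2 * cm@TP / (2 * cm@TP + cm@FP + cm@FN),
                 tolerance = 1e-9)
  }
})

test_that("metrics(confusion(y, y)) is 100% accurate for any labeling", {
  set.seed(8)
  for (rep in 1:5) {
    y <- sample(c("tumor", "normal"), 20, TRUE)
    if (length(unique(y)) < 2) next
    m <- computeMetrics(binaryConfusion(y, y, positive = "tumor"))
    expect_equal(m@accuracy, 100)
    expect_equal(m@dice, 100)
  }
})

test_that("pixel-wise confusion matches per-pixel enumeration", {
  set.seed(17)
  pred <- matrix(sample(0:1, 64, TRUE), 8, 8)
  tru <- matrix(sample(0:1, 64, TRUE), 8, 8)
  tru[1, 1:2] <- 255L
  cm <- segmentationConfusion(pred, tru)
  tp <- fp <- fn <- tn <- 0
  for (i in 1:8) for (j in 1:8) {
    if (tru[i, j] == 255) next
    if (pred[i, j] == 1 && tru[i, j] == 1) tp <- tp + 1
    if (pred[i, j] == 1 && tru[i, j] == 0) fp <- fp + 1
    if (pred[i, j] == 0 && tru[i, j] == 1) fn <- fn + 1
    if (pred[i, j] == 0 && tru[i, j] == 0) tn <- tn + 1
  }
  expect_equal(c(cm@TP, cm@FP, cm@FN, cm@TN), c(tp, fp, fn, tn))
  expect_equal(cm@TP + cm@FP + cm@FN + cm@TN, 62)
  expect_error(segmentationConfusion(pred, tru[1:4, ]), "size")
  # identical masks give dice 100, disjoint non-empty masks dice 0
  expect_equal(diceScore(tru == 1, (tru == 1) * 1L), 100)
  a <- matrix(0L, 4, 4); a[1, 1] <- 1L
  b <- matrix(0L, 4, 4); b[4, 4] <- 1L
  expect_equal(diceScore(a, b), 0)
  expect_equal(diceScore(matrix(0L, 4, 4), matrix(0L, 4, 4)), 100)
})

test_that("record-wise folds are stratified within one image per class", {
  labels <- rep(c("tumor", "normal"), c(50, 50))
  f <- kfoldRecord(labels, k = 10, seed = 2)
  expect_identical(sort(unique(f)), 1:10)
  tab <- table(f, labels)
  expect_true(all(tab == 5))
  # uneven classes: per-fold class counts differ by at most 1
  labels2 <- rep(c("tumor", "normal"), c(37, 63))
  f2 <- kfoldRecord(labels2, k = 10, seed = 3)
  tab2 <- table(f2, labels2)
  expect_lte(diff(range(tab2[, "tumor"])), 1)
  expect_lte(diff(range(tab2[, "normal"])), 1)
  expect_warning(kfoldRecord(rep(c("a", "b"), c(4, 26)), k = 10, seed = 1),
                 "fewer than k")
})

test_that("subject-wise folds never split a subject and stay balanced", {
  subj <- rep(sprintf("S%02d", 1:20), each = 5)
  f <- kfoldSubject(subj, k = 10, seed = 4)
  expect_identical(length(f), 100L)
  # no subject spans folds
  expect_true(all(tapply(f, subj, function(x) length(unique(x))) == 1))
  # 20 equal subjects into 10 folds: 2 subjects / 10 images each
  expect_true(all(table(f) == 10))
  # fold-size spread bounded by the largest subject
  subj2 <- rep(sprintf("S%02d", 1:13), times = c(9, 7, 6, 5, 5, 4, 4, 3, 3,
                                                 2, 2, 2, 1))
  f2 <- kfoldSubject(subj2, k = 5, seed = 5)
  expect_lte(diff(range(table(f2))), 9)
  expect_error(kfoldSubject(rep("S1", 30), k = 10), "distinct subjects")
})

test_that("fold aggregation reports mean and population sd", {
  r1 <- new("MetricsReport", accuracy = 90, sensitivity = 80,
            specificity = 85, precision = 88, dice = 84)
  r2 <- new("MetricsReport", accuracy = 94, sensitivity = 84,
            specificity = 89, precision = 92, dice = 88)
  agg <- aggregateMetrics(list(r1, r2))
  expect_equal(agg$mean[agg$metric == "accuracy"], 92)
  expect_equal(agg$sd[agg$metric == "accuracy"], 2)
})
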