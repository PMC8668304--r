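#' Metrics report
#'
#' Accuracy, sensitivity (recall), specificity, precision and Dice score,
#' all expressed as percentages. The Dice score equals the harmonic mean of
#' precision and recall, equivalently `2TP / (2TP + FP + FN)`. Metrics with
#' a zero denominator are reported as `NaN` (with a warning), never silently
#' as 0 or 100.
#'
#' @slot accuracy,sensitivity,specificity,precision,dice percentages.
#' @seealso [computeMetrics()]
#' @export
setClass("MetricsReport", representation(
  accuracy = "numeric", sensitivity = "numeric", specificity = "numeric",
  precision = "numeric", dice = "numeric"
))

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(paste0("MetricsReport: accuracy %.2f%%, sensitivity %.2f%%, ",
                     "specificity %.2f%%, precision %.2f%%, dice %.2f%%\n"),
              object@accuracy, object@sensitivity, object@specificity,
              object@precision, object@dice))
})

#' Coerce a metrics report to a named numeric vector
#' @param x a [MetricsReport-class].
#' @param mode ignored.
#' @export
setMethod("as.vector", "MetricsReport", function(x, mode = "any") {
  c(accuracy = x@accuracy, sensitivity = x@sensitivity,
    specificity = x@specificity, precision = x@precision, dice = x@dice)
})

# tolerance absorbs binary-representation error, e.g. 0.7 * 1425 = 997.49999...
roundHalfUp <- function(x) floor(x + 0.5 + 1e-9)

#' 70/10/20 train/validation/test split
#'
#' Deterministic counts with randomized membership: the training count is
#' `round-half-up(0.7 n)`, the test count `round-half-up(0.2 n)`, and
#' validation takes the remainder — the rounding convention that reproduces
#' the reference partitions (1425 -> 998/142/285, 1675 -> 1173/167/335,
#' 2470 -> 1729/247/494).
#'
#' @param n number of items (>= 10).
#' @param seed integer seed for membership assignment.
#' @param fractions length-3 target fractions (train, val, test); train and
#'   test are rounded half-up, validation absorbs the remainder.
#' @return a [DatasetSplit-class].
#' @examples
#' s <- splitDataset(1425, seed = 1)
#' c(length(s@trainIdx), length(s@valIdx), length(s@testIdx))
#' @export
splitDataset <- function(n, seed = 1L, fractions = c(0.7, 0.1, 0.2)) {
  if (!is.numeric(n) || n < 10)
    stop("'n' must be >= 10", call. = FALSE)
  n <- as.integer(n)
  nTrain <- as.integer(roundHalfUp(fractions[1] * n))
  nTest <- as.integer(roundHalfUp(fractions[3] * n))
  nVal <- n - nTrain - nTest
  perm <- withSeed(seed, sample.int(n))
  new("DatasetSplit",
      trainIdx = perm[seq_len(nTrain)],
      valIdx = perm[nTrain + seq_len(nVal)],
      testIdx = perm[nTrain + nVal + seq_len(nTest)],
      fractions = fractions, seed = as.integer(seed))
}

#' Binary confusion matrix from label vectors
#'
#' @param yTrue,yPred equal-length vectors over a 2-value label domain.
#' @param positive the label counted as positive.
#' @return a [ConfusionMatrix-class].
#' @export
binaryConfusion <- function(yTrue, yPred, positive = "tumor") {
  if (length(yTrue) != length(yPred))
    stop("'yTrue' and 'yPred' must have equal length", call. = FALSE)
  lv <- unique(c(yTrue, yPred))
  if (length(lv) > 2L)
    stop("labels must come from a 2-value domain, got: ",
         paste(lv, collapse = ", "), call. = FALSE)
  if (!positive %in% lv && length(lv) == 2L)
    stop("'positive' label not present in the labels", call. = FALSE)
  tp <- sum(yTrue == positive & yPred == positive)
  fn <- sum(yTrue == positive & yPred != positive)
  fp <- sum(yTrue != positive & yPred == positive)
  tn <- sum(yTrue != positive & yPred != positive)
  new("ConfusionMatrix", TP = tp, FP = fp, FN = fn, TN = tn,
      positive = as.character(positive))
}

#' Pixel-wise confusion matrix of two masks
#'
#' Counts TP/FP/FN/TN over aligned pixels, excluding pixels whose true
#' label equals `ignoreLabel`. Class 1 is the positive (tumor) class.
#'
#' @param predMask,trueMask aligned integer 0/1 masks (`trueMask` may also
#'   contain `ignoreLabel`).
#' @param ignoreLabel label excluded from the counts (default 255).
#' @return a [ConfusionMatrix-class].
#' @export
segmentationConfusion <- function(predMask, trueMask, ignoreLabel = 255L) {
  if (!is.matrix(predMask) || !is.matrix(trueMask) ||
      !all(dim(predMask) == dim(trueMask)))
    stop("size error: masks must be aligned matrices of equal dimensions",
         call. = FALSE)
  keep <- trueMask != ignoreLabel
  p <- predMask[keep]
  t <- trueMask[keep]
  new("ConfusionMatrix",
      TP = sum(p == 1 & t == 1), FP = sum(p == 1 & t == 0),
      FN = sum(p == 0 & t == 1), TN = sum(p == 0 & t == 0),
      positive = "1")
}

#' Compute classification metrics from a confusion matrix
#'
#' Accuracy `= (TP+TN)/(TP+FN+TN+FP) * 100`; sensitivity (recall)
#' `= TP/(TP+FN)`; specificity `= TN/(TN+FP)`; precision `= TP/(TP+FP)`;
#' Dice (F1) `= 2 * precision * recall / (precision + recall)` — all
#' reported as percentages. A zero denominator yields `NaN` with a warning.
#'
#' @param cm a [ConfusionMatrix-class].
#' @return a [MetricsReport-class].
#' @examples
#' cm <- new("ConfusionMatrix", TP = 50, FP = 5, FN = 10, TN = 220,
#'           positive = "tumor")
#' computeMetrics(cm)
#' @export
computeMetrics <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  tot <- cm@TP + cm@FP + cm@FN + cm@TN
  if (tot == 0)
    stop("degenerate confusion matrix: all counts are zero", call. = FALSE)
  safeDiv <- function(num, den, what) {
    if (den == 0) {
      warning(what, " is undefined (zero denominator); reported as NaN",
              call. = FALSE)
      return(NaN)
    }
    num / den
  }
  acc <- 100 * (cm@TP + cm@TN) / tot
  sens <- 100 * safeDiv(cm@TP, cm@TP + cm@FN, "sensitivity")
  spec <- 100 * safeDiv(cm@TN, cm@TN + cm@FP, "specificity")
  prec <- 100 * safeDiv(cm@TP, cm@TP + cm@FP, "precision")
  dice <- if (is.nan(prec) || is.nan(sens) || (prec + sens) == 0) {
    if (2 * cm@TP + cm@FP + cm@FN == 0) {
      warning("dice is undefined (no positive pixels in either mask); ",
              "reported as NaN", call. = FALSE)
      NaN
    } else 100 * 2 * cm@TP / (2 * cm@TP + cm@FP + cm@FN)
  } else diceFromPrecisionRecall(prec, sens)
  new("MetricsReport", accuracy = acc, sensitivity = sens,
      specificity = spec, precision = prec, dice = dice)
}

#' Dice (F1) score from precision and recall
#'
#' `2 * precision * recall / (precision + recall)`, the harmonic mean;
#' inputs and output on the same scale (fractions or percentages).
#'
#' @param precision,recall non-negative values on a common scale.
#' @return the Dice score.
#' @examples
#' diceFromPrecisionRecall(96.74, 97.80)  # 97.27
#' @export
diceFromPrecisionRecall <- function(precision, recall) {
  2 * precision * recall / (precision + recall)
}

#' Dice overlap of two binary masks
#'
#' `2TP / (2TP + FP + FN)` as a percentage. When both masks are empty the
#' overlap is perfect by convention and 100 is returned (an all-normal image
#' predicted clean scores 100, not 0).
#'
#' @param predMask,trueMask aligned 0/1 masks.
#' @param ignoreLabel true-mask label excluded from the counts.
#' @return the Dice score in \[0, 100\].
#' @export
diceScore <- function(predMask, trueMask, ignoreLabel = 255L) {
  cm <- segmentationConfusion(predMask, trueMask, ignoreLabel)
  den <- 2 * cm@TP + cm@FP + cm@FN
  if (den == 0) return(100)
  100 * 2 * cm@TP / den
}

#' Stratified (record-wise) k-fold assignment
#'
#' Shuffles within each class and deals members round-robin, so per-fold
#' class counts differ by at most one and the folds partition the data.
#'
#' @param labels class label vector (one entry per image).
#' @param k number of folds (default 10; must be <= number of items).
#' @param seed integer seed.
#' @return integer fold assignment in `1..k`, parallel to `labels`.
#' @export
kfoldRecord <- function(labels, k = 10L, seed = 1L) {
  n <- length(labels)
  if (k > n) stop("'k' must be <= number of items", call. = FALSE)
  fold <- integer(n)
  withSeed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k)
        warning("class '", cl, "' has fewer than k = ", k,
                " members; folds assigned best-effort", call. = FALSE)
      fold[idx] <- rep_len(seq_len(k), length(idx))[sample(length(idx))]
    }
  })
  fold
}

#' Subject-wise k-fold assignment
#'
#' Every subject's images land in exactly one fold. Subjects are assigned
#' greedily, largest first, to the currently smallest fold, so fold sizes
#' are as balanced as the subject sizes allow.
#'
#' @param subjectIds subject identifier vector (one entry per image).
#' @param k number of folds (default 10; requires >= k distinct subjects).
#' @param seed integer seed (breaks ties among equal-sized subjects/folds).
#' @return integer fold assignment in `1..k`, parallel to `subjectIds`.
#' @export
kfoldSubject <- function(subjectIds, k = 10L, seed = 1L) {
  subjects <- unique(subjectIds)
  if (length(subjects) < k)
    stop("subject-wise CV needs at least k = ", k, " distinct subjects, got ",
         length(subjects), call. = FALSE)
  sizes <- table(subjectIds)[subjects]
  ord <- withSeed(seed, {
    shuffled <- sample(length(subjects))
    shuffled[order(sizes[shuffled], decreasing = TRUE)]
  })
  foldSize <- numeric(k)
  subjFold <- integer(length(subjects))
  for (s in ord) {
    f <- which.min(foldSize)
    subjFold[s] <- f
    foldSize[f] <- foldSize[f] + sizes[s]
  }
  subjFold[match(subjectIds, subjects)]
}

#' Aggregate metrics over folds or seeds
#'
#' Mean and population standard deviation per metric, the usual
#' `mean ± sd` presentation of cross-validated results.
#'
#' @param reports list of [MetricsReport-class] objects.
#' @return data.frame with columns `metric`, `mean`, `sd`.
#' @export
aggregateMetrics <- function(reports) {
  m <- do.call(rbind, lapply(reports, as.vector))
  popSd <- function(x) sqrt(mean((x - mean(x))^2))
  data.frame(metric = colnames(m), mean = colMeans(m),
             sd = apply(m, 2L, popSd), row.names = NULL)
}
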