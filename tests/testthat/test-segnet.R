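test_that("the network maps H x W inputs to H x W x K probability maps", {
  m <- buildFcnn(seed = 1, filters = 6, decoderFilters = c(4L, 4L))
  img <- matrix(runif(48 * 48), 48, 48)
  p <- predictMask(m, img)
  expect_identical(dim(p$prob), c(48L, 48L, 2L))
  expect_lt(max(abs(apply(p$prob, c(1, 2), sum) - 1)), 1e-6)
  expect_true(all(p$mask %in% c(0L, 1L)))
  expect_error(predictMask(m, matrix(0.5, 50, 50)), "divisible")
  expect_error(buildFcnn(nClasses = 1), ">= 2")
})

test_that("weight initialization is seeded and Glorot-shaped", {
  a <- buildFcnn(seed = 5)
  b <- buildFcnn(seed = 5)
  c <- buildFcnn(seed = 6)
  expect_identical(a@layers, b@layers)
  expect_false(identical(a@layers[[1]]$W, c@layers[[1]]$W))
  # first conv layer parameter count: 64 filters of 3x3x1 plus biases
  l1 <- a@layers[[1]]
  expect_identical(length(l1$W) + length(l1$b), 64L * (3L * 3L * 1L) + 64L)
  # Glorot bound for that layer
  lim <- sqrt(6 / (9 + 9 * 64))
  expect_true(all(abs(l1$W) <= lim))
})

test_that("focal loss reproduces hand-computed values and reduces to
           cross-entropy at gamma 0", {
  # perfect prediction gives zero loss
  perfect <- array(c(0, 1), dim = c(1, 1, 2))
  expect_equal(focalLoss(perfect, matrix(1L, 1, 1),
                         focalLossParams(gamma = 2)), 0, tolerance = 1e-12)
  # single pixel, p_true 0.9, gamma 2, unit weight
  p <- array(c(0.1, 0.9), dim = c(1, 1, 2))
  expect_equal(focalLoss(p, matrix(1L, 1, 1),
                         focalLossParams(gamma = 2, classWeights = 1)),
               0.01 * -log(0.9), tolerance = 1e-12)
  expect_equal(0.01 * -log(0.9), 1.0536e-3, tolerance = 1e-4)
  # gamma 0 equals an independent plain cross-entropy
  set.seed(13)
  K <- 3
  arr <- array(runif(8 * 8 * K), dim = c(8, 8, K))
  tot <- apply(arr, c(1, 2), sum)
  for (k in 1:K) arr[, , k] <- arr[, , k] / tot
  tgt <- matrix(sample(0:(K - 1), 64, TRUE), 8, 8)
  tgt[1, 1:3] <- 255L
  w <- c(1, 2, 0.5)
  expect_equal(focalLoss(arr, tgt, focalLossParams(0, w)),
               oracleCrossEntropy(arr, tgt, w), tolerance = 1e-9)
  # ignore-only target is a degenerate batch
  expect_error(focalLoss(arr, matrix(255L, 8, 8), focalLossParams(0)),
               "degenerate")
})

test_that("focal loss is non-negative, zero only at certainty, and
           decreasing in p_true", {
  params <- focalLossParams(gamma = 2, classWeights = 1)
  ps <- seq(0.05, 0.999, length.out = 30)
  vals <- vapply(ps, function(p)
    focalLoss(array(c(1 - p, p), dim = c(1, 1, 2)), matrix(1L, 1, 1), params),
    numeric(1))
  expect_true(all(vals > 0))
  expect_true(all(diff(vals) < 0))
})

test_that("numerical and analytic focal-loss gradients agree on a 4x4 map", {
  ns <- asNamespace("BrainTumorSeg")
  set.seed(42)
  Z <- matrix(rnorm(16 * 2), 16, 2)
  tgt <- sample(c(0L, 1L, NA), 16, TRUE, prob = c(0.45, 0.45, 0.1))
  for (gamma in c(0, 2, 10)) {
    fl <- ns$focalFromLogits(Z, tgt, gamma, c(1, 1.5))
    num <- Z * 0
    eps <- 1e-6
    for (i in seq_along(Z)) {
      Zp <- Z; Zp[i] <- Zp[i] + eps
      Zm <- Z; Zm[i] <- Zm[i] - eps
      num[i] <- (ns$focalFromLogits(Zp, tgt, gamma, c(1, 1.5))$loss -
                   ns$focalFromLogits(Zm, tgt, gamma, c(1, 1.5))$loss) /
        (2 * eps)
    }
    expect_lt(max(abs(num - fl$dZ)) / max(abs(num)), 1e-4)
  }
})

test_that("backpropagation matches numerical gradients through every layer
           type", {
  ns <- asNamespace("BrainTumorSeg")
  set.seed(42)
  m <- buildFcnn(seed = 1, filters = 4, decoderFilters = c(3L, 3L))
  img <- matrix(rnorm(64), 8, 8)
  msk <- matrix(sample(0:1, 64, TRUE), 8, 8)
  X <- ns$stackImages(list(img))
  tg <- ns$stackTargets(list(msk))
  fw <- ns$nnForward(m@layers, X, 8, 8, 1, training = TRUE)
  fl <- ns$focalFromLogits(fw$out, tg, 2, c(1, 1))
  bw <- ns$nnBackward(fw$layers, fw$caches, fl$dZ)
  eps <- 1e-6
  for (l in seq_along(m@layers)) {
    for (nm in ns$layerParamNames(m@layers[[l]])) {
      ks <- sample(length(m@layers[[l]][[nm]]),
                   min(2, length(m@layers[[l]][[nm]])))
      for (k in ks) {
        lp <- m@layers
        lp[[l]][[nm]][k] <- lp[[l]][[nm]][k] + eps
        f1 <- ns$focalFromLogits(ns$nnForward(lp, X, 8, 8, 1, TRUE)$out,
                                 tg, 2, c(1, 1))$loss
        lp[[l]][[nm]][k] <- lp[[l]][[nm]][k] - 2 * eps
        f2 <- ns$focalFromLogits(ns$nnForward(lp, X, 8, 8, 1, TRUE)$out,
                                 tg, 2, c(1, 1))$loss
        expect_lt(abs((f1 - f2) / (2 * eps) - bw$grads[[l]][[nm]][k]), 1e-6)
      }
    }
  }
})

test_that("short training lowers the loss and is bit-reproducible", {
  ds <- easyDataset(24, 32)
  m <- buildFcnn(seed = 2)
  cfg <- trainingConfig(maxEpochs = 3, seed = 4, focalGamma = 2,
                        minibatchSize = 8)
  r1 <- trainSegmenter(m, ds, cfg)
  expect_lt(tail(r1$history$train_loss, 1), r1$history$train_loss[1])
  r2 <- trainSegmenter(m, ds, cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$model@layers, r2$model@layers)
  expect_error(trainSegmenter(m, ds[integer(0)], cfg), "non-empty")
})
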