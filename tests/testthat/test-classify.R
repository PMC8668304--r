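test_that("the adapted model yields softmax-normalized 2-way outputs", {
  m <- adaptBackbone("mini_inception_scratch", seed = 3)
  for (i in 1:4) {
    set.seed(i)
    r <- predictLabel(m, matrix(runif(40 * 40), 40, 40))
    expect_equal(sum(r$prob), 1, tolerance = 1e-9)
    expect_true(r$label %in% c("tumor", "normal"))
    expect_named(r$prob, c("normal", "tumor"))
  }
  expect_error(adaptBackbone(nClasses = 1), ">= 2")
  expect_error(adaptBackbone("googlenet_pretrained"), "pretrained")
})

test_that("the scratch backbone parameter count matches layer arithmetic", {
  ns <- asNamespace("BrainTumorSeg")
  m <- miniInception(seed = 1)
  conv <- function(k, cin, cout) k * k * cin * cout + cout
  bn <- function(c) 2 * c
  expected <- conv(3, 1, 8) + bn(8) +
    conv(1, 8, 8) + conv(3, 8, 8) + conv(5, 8, 4) + bn(20) +
    conv(1, 20, 12) + conv(3, 20, 12) + conv(5, 20, 6) + bn(30) +
    (30 * 2 + 2)
  expect_identical(ns$parameterCount(m@layers), as.numeric(expected))
})

test_that("input preparation resizes, replicates channels and preserves
           constants", {
  img <- matrix(runif(64 * 64), 64, 64)
  out <- prepareInput(img, 32L)
  expect_identical(dim(out), c(32L, 32L))
  out3 <- prepareInput(img, 24L, channels = 3L)
  expect_identical(dim(out3), c(24L, 24L, 3L))
  expect_identical(out3[, , 1], out3[, , 3])
  # no-op when already at size
  same <- prepareInput(img, 64L)
  expect_identical(same, img)
  # constants survive bilinear interpolation
  expect_equal(prepareInput(matrix(0.7, 50, 50), 32L), matrix(0.7, 32, 32),
               tolerance = 1e-12)
})

test_that("freezing pins the backbone while the head still learns", {
  ns <- asNamespace("BrainTumorSeg")
  ds <- easyDataset(24, 32)
  m <- adaptBackbone("mini_inception_scratch", freezeBackbone = TRUE,
                     seed = 5)
  before <- ns$backboneChecksum(m)
  headBefore <- m@layers[[length(m@layers)]]$W
  r <- trainClassifier(m, ds, transferConfig(epochs = 2, batchSize = 8,
                                             seed = 6))
  expect_identical(ns$backboneChecksum(r$model), before)
  expect_false(identical(r$model@layers[[length(m@layers)]]$W, headBefore))
})

test_that("training is reproducible and learns an easy separation", {
  ds <- easyDataset(40, 32)
  m <- adaptBackbone("mini_inception_scratch", seed = 7)
  cfg <- transferConfig(epochs = 6, batchSize = 10, seed = 8)
  r1 <- trainClassifier(m, ds, cfg)
  r2 <- trainClassifier(m, ds, cfg)
  expect_identical(r1$history, r2$history)
  expect_lt(tail(r1$history$train_loss, 1), r1$history$train_loss[1])
  # single-class data is degenerate
  tumorOnly <- ds[imageLabels(ds) == "tumor"]
  expect_error(trainClassifier(m, tumorOnly, cfg), "degenerate")
})

test_that("prediction is invariant to batch order", {
  ds <- easyDataset(24, 32)
  m <- adaptBackbone("mini_inception_scratch", seed = 9)
  r <- trainClassifier(m, ds, transferConfig(epochs = 2, batchSize = 8,
                                             seed = 10))
  imgs <- images(easyDataset(24, 32))[1:6]
  single <- vapply(imgs, function(im) predictLabel(r$model, im)$label,
                   character(1))
  reversed <- rev(vapply(rev(imgs), function(im)
    predictLabel(r$model, im)$label, character(1)))
  expect_identical(single, reversed)
})
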