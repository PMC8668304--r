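test_that("tumor-free spec yields an all-zero mask and 'normal' label", {
  out <- generatePhantom(quietSpec(tumor = list(present = FALSE, radiusPx = 8)))
  expect_true(all(out$mask == 0L))
  expect_identical(out$label, "normal")
})

test_that("noiseless tumor disk matches a brute-force rasterization", {
  sp <- phantomSpec(128, 128, tumor = list(radiusPx = 20, softnessPx = 0),
                    noise = list(sigma = 0), seed = 3)
  out <- generatePhantom(sp)
  # brute-force per-pixel distance test against the analytic disk
  cy <- (128 + 1) / 2; cx <- cy
  expected <- matrix(0L, 128, 128)
  for (i in 1:128) for (j in 1:128)
    if (sqrt((i - cy)^2 + (j - cx)^2) <= 20) expected[i, j] <- 1L
  expect_identical(out$mask, expected)
  expect_equal(sum(out$mask), pi * 20^2, tolerance = 0.02)
  expect_identical(out$label, "tumor")
})

test_that("phantoms are bit-identical for equal seeds and differ across seeds", {
  a <- generatePhantom(quietSpec(seed = 7))
  b <- generatePhantom(quietSpec(seed = 7))
  c <- generatePhantom(quietSpec(seed = 8))
  expect_identical(a, b)
  expect_false(identical(a$image, c$image))
})

test_that("intensities stay in [0, 1] and tumor is brighter than tissue", {
  for (model in c("gaussian", "rician")) {
    out <- generatePhantom(phantomSpec(64, 64, tumor = list(radiusPx = 8),
                                       noise = list(model = model,
                                                    sigma = 0.08), seed = 4))
    expect_true(all(out$image >= 0 & out$image <= 1))
    tissue <- out$brainMask == 1 & out$mask == 0
    expect_gt(mean(out$image[out$mask == 1]), mean(out$image[tissue]))
  }
})

test_that("tumor that cannot fit inside the brain raises a placement error", {
  sp <- quietSpec(hw = 64)
  sp@tumor$center <- c(6, 6)  # inside the skull ring region
  expect_error(generatePhantom(sp), "placement")
  expect_error(phantomSpec(height = 16, width = 16), "32")
})

test_that("generateDataset honors counts, fractions and subject partition", {
  ds <- generateDataset(20, 0.5, nSubjects = 4, baseSpec = quietSpec(hw = 48,
                        radius = 6), seed = 5)
  expect_equal(length(ds), 20L)
  expect_equal(sum(imageLabels(ds) == "tumor"), 10L)
  expect_equal(length(unique(subjectIds(ds))), 4L)
  expect_true(all(table(subjectIds(ds)) >= 1))
  # mask/label consistency on every item
  hasTumor <- vapply(masks(ds), function(m) any(m == 1L), logical(1))
  expect_identical(imageLabels(ds) == "tumor", hasTumor)
  # odd fractions round
  ds2 <- generateDataset(9, 1 / 3, nSubjects = 2,
                         baseSpec = quietSpec(hw = 48, radius = 6), seed = 5)
  expect_equal(sum(imageLabels(ds2) == "tumor"), 3L)
  expect_error(generateDataset(0, 0.5), "positive")
  expect_error(generateDataset(5, 0.5, nSubjects = 9), "nImages")
})

test_that("datasets are a pure function of (spec, seed)", {
  a <- generateDataset(8, 0.5, 2, quietSpec(hw = 48, radius = 6), seed = 9)
  b <- generateDataset(8, 0.5, 2, quietSpec(hw = 48, radius = 6), seed = 9)
  c <- generateDataset(8, 0.5, 2, quietSpec(hw = 48, radius = 6), seed = 10)
  expect_identical(images(a), images(b))
  expect_identical(masks(a), masks(b))
  expect_false(identical(images(a), images(c)))
})

test_that("writeDataset round-trips images, masks and manifest", {
  d <- withr::local_tempdir()
  ds <- generateDataset(4, 0.5, 2, quietSpec(hw = 48, radius = 6), seed = 2)
  man <- writeDataset(ds, d, format = "png")
  expect_true(file.exists(file.path(d, "manifest.csv")))
  expect_named(man, c("image_path", "mask_path", "label", "subject_id",
                      "modality", "seed"))
  m1 <- readMaskImage(man$mask_path[1])
  expect_identical(m1, masks(ds)[[1]])
  i1 <- readImage2D(man$image_path[1])
  expect_lt(max(abs(i1 - images(ds)[[1]])), 1 / 255)
})
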