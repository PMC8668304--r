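test_that("grayscale conversion applies luminance weights", {
  m <- matrix(runif(36), 6, 6)
  expect_identical(toGrayscale(m), m)
  rgbEqual <- array(rep(m, 3), dim = c(6, 6, 3))
  expect_equal(toGrayscale(rgbEqual), m, tolerance = 1e-12)
  red <- array(0, dim = c(2, 2, 3)); red[, , 1] <- 1
  expect_equal(toGrayscale(red), matrix(0.299, 2, 2))
  expect_error(toGrayscale(array(0, dim = c(2, 2, 2))), "format")
})

test_that("median filter removes impulses and matches the sort oracle", {
  expect_equal(medianFilter3x3(matrix(0.3, 5, 5)), matrix(0.3, 5, 5))
  salted <- matrix(0.3, 7, 7); salted[4, 4] <- 1
  expect_equal(medianFilter3x3(salted), matrix(0.3, 7, 7))
  set.seed(11)
  for (rep in 1:5) {
    img <- matrix(sample(0:99, 256, TRUE), 16, 16)
    expect_identical(medianFilter3x3(img), oracleMedian3x3(img))
  }
  expect_error(medianFilter3x3(matrix(0, 2, 5)), "3x3")
})

test_that("median filter is idempotent on piecewise-constant images", {
  img <- matrix(0.2, 12, 12)
  img[4:9, 4:9] <- 0.8  # 6x6 block, regions >= 3x3
  once <- medianFilter3x3(img)
  expect_identical(medianFilter3x3(once), once)
})

test_that("high-pass mask has the printed coefficients summing to zero", {
  k <- highPassKernel()
  expect_identical(k[1, ], c(-1, 2, -1))
  expect_identical(k[2, ], c(0, 0, 0))
  expect_identical(k[3, ], c(1, -2, 1))
  expect_identical(sum(k), 0)
})

test_that("edge enhancement is the identity on constants and matches the
           correlation oracle", {
  for (c0 in c(0, 0.4, 1))
    expect_equal(enhanceEdges(matrix(c0, 9, 9)), matrix(c0, 9, 9))
  # two-band image with a horizontal edge, checked against per-pixel oracle
  band <- rbind(matrix(0.2, 4, 8), matrix(0.7, 4, 8))
  k <- highPassKernel()
  expected <- pmin(pmax(band + oracleCorrelate3x3(band, k), 0), 1)
  expect_equal(enhanceEdges(band), expected, tolerance = 1e-12)
  # mirrored input checked against the oracle too (the mask is asymmetric,
  # so the responses differ but both must match the correlation definition)
  mir <- band[, ncol(band):1]
  expect_equal(enhanceEdges(mir),
               pmin(pmax(mir + oracleCorrelate3x3(mir, k), 0), 1),
               tolerance = 1e-12)
  set.seed(3)
  img <- matrix(runif(100, 0.2, 0.8), 10, 10)
  expect_equal(enhanceEdges(img),
               pmin(pmax(img + oracleCorrelate3x3(img, k), 0), 1),
               tolerance = 1e-12)
})

test_that("filters preserve shape and produce finite values", {
  set.seed(4)
  img <- matrix(runif(15 * 11), 15, 11)
  for (f in list(medianFilter3x3, enhanceEdges)) {
    out <- f(img)
    expect_identical(dim(out), dim(img))
    expect_true(all(is.finite(out)))
  }
})

test_that("z-score normalization standardizes to mean 0, variance 1", {
  set.seed(5)
  img <- matrix(rnorm(400, 3, 2), 20, 20)
  r <- normalizeZscore(img)
  expect_lt(abs(mean(r$image)), 1e-9)
  expect_lt(abs(mean(r$image^2) - 1), 1e-6)
  # fixed point: an already-standardized image is unchanged
  r2 <- normalizeZscore(r$image)
  expect_equal(r2$image, r$image, tolerance = 1e-9)
  # two-pixel symmetry
  r3 <- normalizeZscore(matrix(c(0, 2), 1, 2))
  expect_equal(as.vector(r3$image), c(-1, 1))
  expect_error(normalizeZscore(matrix(1, 4, 4)), "degenerate|constant")
})

test_that("dataset normalization supports image and subject scopes", {
  ds <- easyDataset(8, 32)
  ni <- normalizeDataset(ds, "image")
  for (im in images(ni)) {
    expect_lt(abs(mean(im)), 1e-9)
    expect_lt(abs(mean(im^2) - 1), 1e-6)
  }
  nsub <- normalizeDataset(ds, "subject")
  for (s in unique(subjectIds(nsub))) {
    v <- unlist(images(nsub)[subjectIds(nsub) == s])
    expect_lt(abs(mean(v)), 1e-9)
    expect_lt(abs(mean(v^2) - 1), 1e-6)
  }
})
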