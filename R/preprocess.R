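#' Convert a raster to single-channel grayscale
#'
#' 3-channel inputs are reduced with the standard luminance weights
#' 0.299 R + 0.587 G + 0.114 B; single-channel inputs pass through unchanged.
#'
#' @param image a numeric matrix (1 channel) or an H x W x 3 array.
#' @return a numeric matrix (Image2D).
#' @export
toGrayscale <- function(image) {
  if (is.matrix(image)) return(image)
  if (is.array(image) && length(dim(image)) == 3L) {
    nc <- dim(image)[3]
    if (nc == 1L) return(image[, , 1L])
    if (nc == 3L)
      return(0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L])
  }
  stop("format error: expected a 2-D matrix or an H x W x {1,3} array",
       call. = FALSE)
}

# gather the 9 neighbors of every pixel under edge replication;
# returns an (H*W) x 9 matrix of intensities
replicatedNeighbors <- function(image) {
  h <- nrow(image); w <- ncol(image)
  ri <- matrix(seq_len(h), h, w)
  ci <- matrix(seq_len(w), h, w, byrow = TRUE)
  out <- matrix(0, h * w, 9L)
  k <- 0L
  for (dj in -1:1) for (di in -1:1) {
    k <- k + 1L
    r <- pmin(pmax(ri + di, 1L), h)
    c <- pmin(pmax(ci + dj, 1L), w)
    out[, k] <- image[cbind(as.vector(r), as.vector(c))]
  }
  out
}

#' 3x3 median filter
#'
#' Replaces every pixel by the median of its 3x3 neighborhood, the standard
#' nonlinear denoising step that removes impulse noise while preserving
#' edges. Borders are handled by edge replication; output shape equals input
#' shape.
#'
#' @param image a numeric matrix with both dimensions >= 3.
#' @return the filtered matrix.
#' @export
medianFilter3x3 <- function(image) {
  assertImage2D(image, minDim = 3L)
  nb <- replicatedNeighbors(image)
  # median of 9 = 5th order statistic, column-wise partial sorts
  m <- matrix(apply(nb, 1L, function(v) sort.int(v, partial = 5L)[5L]),
              nrow(image), ncol(image))
  m
}

#' The 3x3 high-pass filter mask
#'
#' Coefficient rows are (-1, 2, -1), (0, 0, 0), (1, -2, 1); the coefficients
#' sum to zero, so the response to any constant image is zero.
#'
#' @return a 3x3 numeric matrix.
#' @export
highPassKernel <- function() {
  matrix(c(-1, 2, -1,
            0, 0,  0,
            1, -2, 1), 3, 3, byrow = TRUE)
}

#' High-pass edge enhancement
#'
#' Correlates the image with the high-pass mask of [highPassKernel()] (mask
#' applied as printed, not flipped) under edge replication, adds the edge
#' response to the original image, and clips to `range`.
#'
#' @param image a numeric matrix with both dimensions >= 3.
#' @param range declared intensity range to clip the result to.
#' @return the enhanced matrix, same shape, values within `range`.
#' @export
enhanceEdges <- function(image, range = c(0, 1)) {
  assertImage2D(image, minDim = 3L)
  nb <- replicatedNeighbors(image)
  # replicatedNeighbors enumerates (di, dj) with di fastest, i.e. column-major
  # over the kernel; match that ordering
  k <- as.vector(highPassKernel())
  resp <- matrix(nb %*% k, nrow(image), ncol(image))
  pmin(pmax(image + resp, range[1]), range[2])
}

#' Z-score intensity normalization
#'
#' Standardizes an image to mean 0 and variance 1 using its own mean and
#' population standard deviation, the normalization applied to network
#' inputs before training and inference.
#'
#' @param image a numeric matrix with at least 2 distinct values.
#' @return list with `image` (the standardized matrix) and `params` (list
#'   with `mu` and `sigma`).
#' @export
normalizeZscore <- function(image) {
  assertImage2D(image)
  mu <- mean(image)
  sigma <- sqrt(mean((image - mu)^2))
  if (sigma == 0)
    stop("degenerate input: constant image has zero variance and cannot be ",
         "z-score normalized", call. = FALSE)
  list(image = (image - mu) / sigma, params = list(mu = mu, sigma = sigma))
}

#' Normalize a dataset's images per image or per subject
#'
#' Per-image scope standardizes every image with its own mean and
#' population sd; per-subject scope pools the statistics over all images of
#' a subject (the per-patient analogue when several slices share a
#' subject).
#'
#' @param dataset a [PhantomDataset-class].
#' @param scope `"image"` or `"subject"`.
#' @return the dataset with standardized images.
#' @export
normalizeDataset <- function(dataset, scope = c("image", "subject")) {
  scope <- match.arg(scope)
  stopifnot(is(dataset, "PhantomDataset"))
  if (scope == "image") {
    dataset@images <- lapply(dataset@images,
                             function(im) normalizeZscore(im)$image)
  } else {
    for (s in unique(dataset@subjectIds)) {
      idx <- which(dataset@subjectIds == s)
      v <- unlist(dataset@images[idx])
      mu <- mean(v)
      sigma <- sqrt(mean((v - mu)^2))
      if (sigma == 0)
        stop("degenerate input: subject '", s, "' has constant intensity",
             call. = FALSE)
      dataset@images[idx] <- lapply(dataset@images[idx],
                                    function(im) (im - mu) / sigma)
    }
  }
  dataset
}

#' Full preprocessing chain
#'
#' Grayscale conversion, optional 3x3 median filtering, optional high-pass
#' edge enhancement, in the pipeline's stage order.
#'
#' @param image input raster (matrix or H x W x 3 array).
#' @param median apply the median filter.
#' @param edgeEnhance apply edge enhancement.
#' @param range intensity range for clipping after edge addition.
#' @return a numeric matrix.
#' @export
preprocessImage <- function(image, median = TRUE, edgeEnhance = TRUE,
                            range = c(0, 1)) {
  img <- toGrayscale(image)
  if (median) img <- medianFilter3x3(img)
  if (edgeEnhance) img <- enhanceEdges(img, range = range)
  img
}
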