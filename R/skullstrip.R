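# Two-threshold (three-class) Otsu on a 256-bin histogram of [0, 1]
# intensities: head MR slices are trimodal (background, tissue, bright
# skull/lesion), and the lower of the two variance-maximizing thresholds is
# the background/head cut. Exhaustive search over bin pairs.
otsuLowerThreshold <- function(image, nbins = 256L) {
  br <- seq(0, 1, length.out = nbins + 1L)
  h <- tabulate(findInterval(image, br, rightmost.closed = TRUE),
                nbins = nbins)
  p <- h / sum(h)
  mids <- (br[-1L] + br[-(nbins + 1L)]) / 2
  cw <- cumsum(p)
  cm <- cumsum(p * mids)
  totalMean <- cm[nbins]
  best <- -Inf; bestT1 <- 1L
  for (t1 in 1L:(nbins - 2L)) {
    w1 <- cw[t1]; m1 <- cm[t1]
    if (w1 <= 0) next
    for (t2 in (t1 + 1L):(nbins - 1L)) {
      w2 <- cw[t2] - w1; w3 <- 1 - cw[t2]
      if (w2 <= 0 || w3 <= 0) next
      m2 <- cm[t2] - m1; m3 <- totalMean - cm[t2]
      v <- m1^2 / w1 + m2^2 / w2 + m3^2 / w3
      if (v > best) { best <- v; bestT1 <- t1 }
    }
  }
  br[bestT1 + 1L]
}

#' Skull stripping by thresholding and morphology
#'
#' Separates brain tissue from the skull ring and background: an automatic
#' global threshold on the intensity histogram (two-threshold Otsu, lower
#' cut — head slices are trimodal: background, tissue, bright
#' skull/lesion), binary
#' opening (disc radius `openingRadius`) to detach the thin skull ring and
#' clean noise bridges, retention of the largest connected component, then
#' binary closing and hole filling. Pixels outside the resulting brain mask
#' are zeroed. The stage is deliberately self-contained so a different brain
#' extractor can be substituted for real data.
#'
#' @param image a preprocessed numeric matrix with intensities in \[0, 1\].
#' @param openingRadius disc radius (px) of the binary opening (default 2).
#' @param closingRadius disc radius (px) of the binary closing (default 3).
#' @param connectivity connectivity for component labeling, 4 or 8 (default 8).
#' @return list with `image` (the masked image) and `mask` (integer 0/1
#'   brain mask with exactly one connected foreground component and no holes).
#' @export
stripSkull <- function(image, openingRadius = 2L, closingRadius = 3L,
                       connectivity = 8L) {
  assertImage2D(image, minDim = 8L)
  rng <- range(image)
  if (rng[1] < 0 || rng[2] > 1)
    stop("stripSkull expects intensities in [0, 1]", call. = FALSE)
  if (rng[2] == rng[1])
    stop("skull stripping failed: image is constant, no foreground to ",
         "separate", call. = FALSE)
  thr <- otsuLowerThreshold(image)
  bin <- image > thr
  if (!any(bin))
    stop("skull stripping failed: empty foreground after automatic threshold (",
         signif(thr, 4), ")", call. = FALSE)
  brush <- function(r) EBImage::makeBrush(2L * as.integer(r) + 1L, "disc")
  opened <- EBImage::opening(EBImage::Image(bin * 1), brush(openingRadius))
  om <- matrix(as.integer(opened > 0.5), nrow(image), ncol(image))
  if (!any(om == 1L))
    stop("skull stripping failed: foreground vanished after opening; ",
         "reduce 'openingRadius'", call. = FALSE)
  lab <- labelComponents(om, connectivity = connectivity)
  areas <- tabulate(lab[lab > 0L])
  biggest <- which.max(areas)
  comp <- matrix(as.integer(lab == biggest), nrow(image), ncol(image))
  closed <- EBImage::closing(EBImage::Image(comp * 1), brush(closingRadius))
  filled <- EBImage::fillHull(closed > 0.5)
  mask <- matrix(as.integer(filled), nrow(image), ncol(image))
  # closing can reconnect stray specks; keep the largest component again
  lab2 <- labelComponents(mask, connectivity = connectivity)
  if (max(lab2) > 1L) {
    areas2 <- tabulate(lab2[lab2 > 0L])
    mask <- matrix(as.integer(lab2 == which.max(areas2)),
                   nrow(image), ncol(image))
    mask <- matrix(as.integer(EBImage::fillHull(EBImage::Image(mask) > 0.5)),
                   nrow(image), ncol(image))
  }
  list(image = image * mask, mask = mask)
}
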