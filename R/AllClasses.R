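#' Synthetic brain phantom specification
#'
#' Parameters for one synthetic 2-D brain-like MR slice: a bright skull ring,
#' a thin dark CSF gap, textured brain tissue, an optional hyperintense tumor
#' disk with a soft rim, and additive Gaussian or Rician noise. All intensities
#' are on \[0, 1\].
#'
#' @slot height,width image dimensions in pixels.
#' @slot skullRing list with `innerRadiusFrac` (brain radius as a fraction of
#'   the half-image), `thicknessPx`, `intensity`, and `gapPx` (dark CSF gap
#'   between tissue and ring).
#' @slot brainTissue list with `meanIntensity` and `textureSd`.
#' @slot tumor list with `present`, `center` (row, col; `NA` for image
#'   center), `radiusPx`, `intensity`, `softnessPx`.
#' @slot noise list with `model` (`"gaussian"` or `"rician"`) and `sigma`.
#' @slot modalityTag one of `"T1"`, `"T2"`, `"T1CE"`, `"FLAIR"` (metadata that
#'   modulates the intensity profile, not a separate channel).
#' @slot subjectId opaque subject identifier.
#' @slot seed integer seed; the phantom is a pure function of (spec, seed).
#' @seealso [phantomSpec()], [generatePhantom()]
#' @export
setClass("PhantomSpec", representation(
  height = "integer", width = "integer",
  skullRing = "list", brainTissue = "list", tumor = "list", noise = "list",
  modalityTag = "character", subjectId = "character", seed = "integer"
))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@height < 32L || object@width < 32L)
    msg <- c(msg, "height and width must be >= 32")
  if (!object@noise$model %in% c("gaussian", "rician"))
    msg <- c(msg, "noise model must be 'gaussian' or 'rician'")
  if (object@noise$sigma < 0) msg <- c(msg, "noise sigma must be >= 0")
  if (!object@modalityTag %in% c("T1", "T2", "T1CE", "FLAIR"))
    msg <- c(msg, "modalityTag must be one of T1, T2, T1CE, FLAIR")
  if (isTRUE(object@tumor$present) &&
      object@tumor$radiusPx >= min(object@height, object@width) / 2)
    msg <- c(msg, "tumor radius must be < min(height, width)/2")
  if (length(msg)) msg else TRUE
})

#' Collection of generated phantoms with ground truth
#'
#' Parallel lists of images, pixel masks, image-level labels, subject IDs and
#' modality tags. The label is `"tumor"` iff the paired mask contains at least
#' one tumor pixel.
#'
#' @slot images list of numeric matrices (Image2D).
#' @slot masks list of integer matrices (0 background, 1 tumor).
#' @slot labels character vector, `"tumor"` or `"normal"`.
#' @slot subjectIds,modalityTags character vectors parallel to `images`.
#' @slot seed integer seed the dataset was generated from.
#' @seealso [generateDataset()]
#' @export
setClass("PhantomDataset", representation(
  images = "list", masks = "list", labels = "character",
  subjectIds = "character", modalityTags = "character", seed = "integer"
))

setValidity("PhantomDataset", function(object) {
  n <- length(object@images)
  msg <- character()
  if (length(object@masks) != n || length(object@labels) != n ||
      length(object@subjectIds) != n || length(object@modalityTags) != n)
    msg <- c(msg, "all parallel lists must have equal length")
  if (n > 0) {
    hasTumor <- vapply(object@masks, function(m) any(m == 1L), logical(1))
    if (!all((object@labels == "tumor") == hasTumor))
      msg <- c(msg, "label must be 'tumor' iff the mask has >= 1 tumor pixel")
  }
  if (length(msg)) msg else TRUE
})

#' 2x2 confusion matrix
#'
#' Counts of true positives, false positives, false negatives and true
#' negatives for a binary decision (image-level labels or pixels).
#'
#' @slot TP,FP,FN,TN non-negative counts.
#' @slot positive the label counted as positive.
#' @seealso [binaryConfusion()], [computeMetrics()]
#' @export
setClass("ConfusionMatrix", representation(
  TP = "numeric", FP = "numeric", FN = "numeric", TN = "numeric",
  positive = "character"
))

setValidity("ConfusionMatrix", function(object) {
  v <- c(object@TP, object@FP, object@FN, object@TN)
  if (any(v < 0) || any(v != round(v))) "counts must be non-negative integers" else TRUE
})

#' Train/validation/test index split
#'
#' @slot trainIdx,valIdx,testIdx disjoint integer index vectors covering 1..n.
#' @slot fractions numeric length-3 target fractions (train, val, test).
#' @slot seed integer seed used for membership assignment.
#' @seealso [splitDataset()]
#' @export
setClass("DatasetSplit", representation(
  trainIdx = "integer", valIdx = "integer", testIdx = "integer",
  fractions = "numeric", seed = "integer"
))

setValidity("DatasetSplit", function(object) {
  all_ <- sort(c(object@trainIdx, object@valIdx, object@testIdx))
  if (!identical(all_, seq_along(all_)))
    "train/val/test indices must partition 1..n" else TRUE
})

#' Segmentation training configuration
#'
#' Hyperparameters of the pixel-classification training loop: Adam with
#' learning rate 0.001, minibatch size 30, at most 20 epochs, per-epoch
#' shuffling, Glorot weight initialization, and a focal loss with focusing
#' value `focalGamma` (default 10; smaller values such as 2 are numerically
#' tamer and are recommended when the default proves unstable).
#'
#' @slot learningRate,minibatchSize,maxEpochs,focalGamma,validationFraction,seed
#'   see [trainingConfig()].
#' @slot shuffleEachEpoch logical.
#' @slot patience consecutive validation checks above the running minimum
#'   loss that trigger early stopping.
#' @export
setClass("TrainingConfig", representation(
  learningRate = "numeric", minibatchSize = "integer", maxEpochs = "integer",
  shuffleEachEpoch = "logical", focalGamma = "numeric", seed = "integer",
  validationFraction = "numeric", patience = "integer"
))

setValidity("TrainingConfig", function(object) {
  msg <- character()
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@minibatchSize < 1L) msg <- c(msg, "minibatchSize must be >= 1")
  if (object@maxEpochs < 1L) msg <- c(msg, "maxEpochs must be >= 1")
  if (object@focalGamma < 0) msg <- c(msg, "focalGamma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Focal loss parameters
#'
#' @slot gamma focusing exponent (>= 0); 0 reduces the loss to weighted
#'   cross-entropy.
#' @slot classWeights per-class weights (>= 0), recycled to the number of
#'   classes; by default inverse class frequency is used at training time.
#' @slot ignoreLabel mask label whose pixels contribute nothing to the loss.
#' @seealso [focalLoss()]
#' @export
setClass("FocalLossParams", representation(
  gamma = "numeric", classWeights = "numeric", ignoreLabel = "integer"
))

setValidity("FocalLossParams", function(object) {
  if (object@gamma < 0) return("gamma must be >= 0")
  if (any(object@classWeights < 0)) return("classWeights must be >= 0")
  TRUE
})

#' Fully convolutional segmentation network
#'
#' Encoder of three (conv 64 filters, 3x3, stride 1, pad 1) + batch-norm +
#' ReLU blocks with 2x2 max-pooling after the first two; decoder of one
#' transposed convolution per pooling stage back to input resolution; 1x1
#' convolution head with per-pixel softmax over classes.
#'
#' @slot layers internal layer list (weights, batch-norm statistics).
#' @slot nClasses number of output classes.
#' @slot inChannels input channel count.
#' @slot poolFactor total spatial downsampling factor of the encoder.
#' @slot trained logical.
#' @slot config the [TrainingConfig-class] used in training (if trained).
#' @export
setClass("FcnnModel", representation(
  layers = "list", nClasses = "integer", inChannels = "integer",
  poolFactor = "integer", trained = "logical", config = "ANY"
))

#' Binary image classifier with a replaceable backbone
#'
#' Internal layer list with the backbone feature extractor first and the
#' fully connected classification head (preceded by dropout) last;
#' [adaptBackbone()] replaces the head and optionally freezes the backbone.
#'
#' @slot layers internal layer list; the final layer is the head.
#' @slot inputSize square input side length in pixels.
#' @slot inChannels input channels expected by the backbone.
#' @slot frozen logical; whether backbone parameters are frozen.
#' @slot classes label names, `c("normal", "tumor")`.
#' @slot trained logical.
#' @export
setClass("ClassifierModel", representation(
  layers = "list", inputSize = "integer", inChannels = "integer",
  frozen = "logical", classes = "character", trained = "logical"
))

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec %dx%d [%s] subject=%s seed=%d\n",
              object@height, object@width, object@modalityTag,
              object@subjectId, object@seed))
  cat(sprintf("  tumor: %s", if (isTRUE(object@tumor$present))
    sprintf("r=%.1fpx I=%.2f", object@tumor$radiusPx, object@tumor$intensity)
    else "absent"), "\n")
  cat(sprintf("  noise: %s sigma=%.3f\n", object@noise$model, object@noise$sigma))
})

setMethod("show", "PhantomDataset", function(object) {
  n <- length(object@images)
  cat(sprintf("PhantomDataset: %d images, %d tumor / %d normal, %d subjects\n",
              n, sum(object@labels == "tumor"), sum(object@labels == "normal"),
              length(unique(object@subjectIds))))
  if (n > 0)
    cat(sprintf("  image size %dx%d, modalities: %s\n",
                nrow(object@images[[1]]), ncol(object@images[[1]]),
                paste(unique(object@modalityTags), collapse = ", ")))
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat(sprintf("ConfusionMatrix (positive = '%s')\n", object@positive))
  m <- matrix(c(object@TP, object@FN, object@FP, object@TN), 2, 2,
              dimnames = list(actual = c("pos", "neg"),
                              predicted = c("pos", "neg")))
  print(m)
})

setMethod("show", "FcnnModel", function(object) {
  cat(sprintf("FcnnModel: %d classes, pool factor %d, %s\n",
              object@nClasses, object@poolFactor,
              if (object@trained) "trained" else "untrained"))
  cat(sprintf("  %d parameter tensors, %d weights\n",
              length(parameterList(object@layers)),
              parameterCount(object@layers)))
})

setMethod("show", "ClassifierModel", function(object) {
  cat(sprintf("ClassifierModel: input %dx%dx%d, %s backbone, %s\n",
              object@inputSize, object@inputSize, object@inChannels,
              if (object@frozen) "frozen" else "trainable",
              if (object@trained) "trained" else "untrained"))
})

#' Accessors for phantom datasets
#'
#' @param x a [PhantomDataset-class].
#' @return `images()` and `masks()` return lists of matrices; `labels()`,
#'   `subjectIds()` and `modalityTags()` return character vectors parallel to
#'   the images.
#' @export
images <- function(x) x@images
#' @rdname images
#' @export
masks <- function(x) x@masks
#' @rdname images
#' @export
imageLabels <- function(x) x@labels
#' @rdname images
#' @export
subjectIds <- function(x) x@subjectIds
#' @rdname images
#' @export
modalityTags <- function(x) x@modalityTags

#' Number of images in a phantom dataset
#' @param x a [PhantomDataset-class].
#' @export
setMethod("length", "PhantomDataset", function(x) length(x@images))

#' Subset a phantom dataset by image index
#' @param x a [PhantomDataset-class].
#' @param i integer or logical index.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "PhantomDataset", function(x, i, j, ..., drop = TRUE) {
  new("PhantomDataset",
      images = x@images[i], masks = x@masks[i], labels = x@labels[i],
      subjectIds = x@subjectIds[i], modalityTags = x@modalityTags[i],
      seed = x@seed)
})

#' Coerce a confusion matrix to a base 2x2 matrix
#' @param x a [ConfusionMatrix-class].
#' @param ... ignored.
#' @export
setMethod("as.matrix", "ConfusionMatrix", function(x, ...) {
  matrix(c(x@TP, x@FN, x@FP, x@TN), 2, 2,
         dimnames = list(actual = c("positive", "negative"),
                         predicted = c("positive", "negative")))
})
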