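#' Build a compact inception-style backbone from scratch
#'
#' A small GoogleNet-flavored classifier usable without any pretrained
#' weights: a 3x3 stem convolution, two inception blocks (parallel 1x1, 3x3
#' and 5x5 convolutions, channel-concatenated) each followed by batch
#' normalization and ReLU, max-pooling between stages, global average
#' pooling, dropout, and a fully connected 2-way head.
#'
#' @param inputSize square input side in pixels (must be divisible by 4;
#'   default 32).
#' @param inChannels input channels (default 1).
#' @param seed integer seed for Glorot initialization.
#' @param dropoutRate dropout probability before the head (default 0.5).
#' @return an untrained [ClassifierModel-class].
#' @export
miniInception <- function(inputSize = 32L, inChannels = 1L, seed = 1L,
                          dropoutRate = 0.5) {
  if (inputSize %% 4L != 0L)
    stop("'inputSize' must be divisible by 4", call. = FALSE)
  layers <- withSeed(seed, list(
    layerConv(3L, inChannels, 8L), layerBN(8L), layerReLU(), layerPool(),
    layerInception(8L, c(8L, 8L, 4L)), layerBN(20L), layerReLU(),
    layerPool(),
    layerInception(20L, c(12L, 12L, 6L)), layerBN(30L), layerReLU(),
    layerGAP(), layerDropout(dropoutRate),
    layerFC(30L, 2L)
  ))
  new("ClassifierModel", layers = layers, inputSize = as.integer(inputSize),
      inChannels = as.integer(inChannels), frozen = FALSE,
      classes = c("normal", "tumor"), trained = FALSE)
}

#' Adapt a backbone for binary classification
#'
#' Implements the transfer-learning head replacement: the final fully
#' connected layer is replaced by a fresh Glorot-initialized `nClasses`-way
#' layer (dropout before it is kept), and the earlier layers are optionally
#' frozen so fine-tuning only updates the head.
#'
#' @param backbone either `"mini_inception_scratch"` (builds
#'   [miniInception()]), an existing [ClassifierModel-class] to adapt, or
#'   `"googlenet_pretrained"` — the latter requires supplying the pretrained
#'   network as a `ClassifierModel` via `pretrained` since no weights are
#'   bundled.
#' @param nClasses number of output classes (>= 2).
#' @param freezeBackbone freeze every layer except the new head.
#' @param seed seed for head initialization (and the backbone, if built here).
#' @param pretrained optional [ClassifierModel-class] carrying externally
#'   pretrained weights, used when `backbone = "googlenet_pretrained"`.
#' @return a [ClassifierModel-class] ready for [trainClassifier()].
#' @export
adaptBackbone <- function(backbone = "mini_inception_scratch", nClasses = 2L,
                          freezeBackbone = FALSE, seed = 1L,
                          pretrained = NULL) {
  if (nClasses < 2L) stop("'nClasses' must be >= 2", call. = FALSE)
  model <- if (is(backbone, "ClassifierModel")) backbone
  else if (identical(backbone, "mini_inception_scratch"))
    miniInception(seed = seed)
  else if (identical(backbone, "googlenet_pretrained")) {
    if (!is(pretrained, "ClassifierModel"))
      stop("backbone 'googlenet_pretrained' needs externally pretrained ",
           "weights passed as a ClassifierModel via 'pretrained'; no ",
           "pretrained weights are bundled", call. = FALSE)
    pretrained
  } else stop("unknown backbone: ", backbone, call. = FALSE)

  nl <- length(model@layers)
  if (model@layers[[nl]]$type != "fc")
    stop("backbone must end in a replaceable fully connected head",
         call. = FALSE)
  cin <- model@layers[[nl]]$cin
  model@layers[[nl]] <- withSeed(deriveSeed(seed, "clf-head"),
                                 layerFC(cin, nClasses))
  if (freezeBackbone) {
    for (i in seq_len(nl - 1L)) model@layers[[i]]$frozen <- TRUE
    model@frozen <- TRUE
  }
  model@trained <- FALSE
  model
}

#' Prepare an image for a classification backbone
#'
#' Bilinear resize to `inputSize` x `inputSize`; for 3-channel backbones the
#' grayscale plane is replicated across channels. Constant images stay
#' constant under the resize.
#'
#' @param image a numeric matrix.
#' @param inputSize target side length in pixels.
#' @param channels 1 (scratch backbone) or 3 (pretrained-style backbone).
#' @return a matrix (`channels = 1`) or H x W x 3 array.
#' @export
prepareInput <- function(image, inputSize = 32L, channels = 1L) {
  assertImage2D(image)
  if (nrow(image) != inputSize || ncol(image) != inputSize) {
    rs <- EBImage::imageData(EBImage::resize(EBImage::Image(image),
                                             w = inputSize, h = inputSize))
    image <- matrix(as.numeric(rs), inputSize, inputSize)
  }
  if (channels == 3L)
    array(rep(image, 3L), dim = c(inputSize, inputSize, 3L))
  else image
}

#' Construct a transfer-learning training configuration
#'
#' @param fineTuneLr Adam learning rate for fine-tuning (default 0.001).
#' @param epochs maximum epochs (default 15).
#' @param batchSize images per minibatch (default 30).
#' @param seed integer seed.
#' @param validationFraction held-out fraction for per-epoch validation.
#' @param patience early-stopping patience (consecutive validation checks
#'   above the running minimum loss).
#' @return a plain list of class `"TransferConfig"`.
#' @export
transferConfig <- function(fineTuneLr = 0.001, epochs = 15L, batchSize = 30L,
                           seed = 1L, validationFraction = 0.1,
                           patience = 10L) {
  stopifnot(fineTuneLr > 0, epochs >= 1, batchSize >= 1)
  structure(list(fineTuneLr = fineTuneLr, epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize), seed = as.integer(seed),
                 validationFraction = validationFraction,
                 patience = as.integer(patience)),
            class = "TransferConfig")
}

clfBatch <- function(model, imgs) {
  stackImages(lapply(imgs, prepareInput, inputSize = model@inputSize,
                     channels = 1L))
}

clfForwardLoss <- function(layers, X, y, n, h, w, training) {
  fw <- nnForward(layers, X, h, w, n, training = training)
  fl <- focalFromLogits(fw$out, y, gamma = 0, weights = c(1, 1))
  pred <- max.col(fl$prob, ties.method = "first") - 1L
  list(fw = fw, fl = fl, acc = mean(pred == y))
}

#' Train the binary tumor/normal classifier
#'
#' Minibatch Adam with cross-entropy on the 2-way head (dropout active
#' during training only). Per-epoch training/validation loss and accuracy
#' are recorded; early stopping mirrors [trainSegmenter()]. Fully
#' reproducible from `config$seed`.
#'
#' @param model a [ClassifierModel-class] (see [adaptBackbone()]).
#' @param data a labeled [PhantomDataset-class] containing both classes.
#' @param config a [transferConfig()].
#' @param valData optional explicit validation [PhantomDataset-class].
#' @return list with `model` and `history` (epoch, train_loss, val_loss,
#'   train_acc, val_acc).
#' @export
trainClassifier <- function(model, data, config = transferConfig(),
                            valData = NULL) {
  stopifnot(is(model, "ClassifierModel"), inherits(config, "TransferConfig"))
  if (!is(data, "PhantomDataset") || length(data) == 0L)
    stop("'data' must be a non-empty PhantomDataset", call. = FALSE)
  if (length(unique(data@labels)) < 2L)
    stop("degenerate data: training requires both 'tumor' and 'normal' ",
         "images", call. = FALSE)
  s <- model@inputSize

  withSeed(config$seed, {
    if (is.null(valData)) {
      nVal <- max(1L, round(length(data) * config$validationFraction))
      vi <- sample(length(data), nVal)
      valData <- data[vi]
      data <- data[-vi]
    }
    yTrain <- as.integer(data@labels == "tumor")
    yVal <- as.integer(valData@labels == "tumor")
    Xval <- clfBatch(model, valData@images)
    layers <- model@layers
    state <- adamInit(layers)
    n <- length(data)
    bs <- min(config$batchSize, n)
    hist <- vector("list", config$epochs)
    bestVal <- Inf; bad <- 0L; t <- 0L
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(n)
      epLoss <- 0; epAcc <- 0; nb <- 0L
      for (start in seq(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        X <- clfBatch(model, data@images[idx])
        r <- clfForwardLoss(layers, X, yTrain[idx], length(idx), s, s,
                            training = TRUE)
        layers <- r$fw$layers
        bw <- nnBackward(layers, r$fw$caches, r$fl$dZ)
        t <- t + 1L
        up <- adamStep(layers, bw$grads, state, config$fineTuneLr, t)
        layers <- up$layers
        state <- up$state
        epLoss <- epLoss + r$fl$loss; epAcc <- epAcc + r$acc; nb <- nb + 1L
      }
      vr <- clfForwardLoss(layers, Xval, yVal, length(valData), s, s,
                           training = FALSE)
      hist[[epoch]] <- data.frame(
        epoch = epoch, train_loss = epLoss / nb, val_loss = vr$fl$loss,
        train_acc = epAcc / nb, val_acc = vr$acc)
      if (vr$fl$loss < bestVal) {
        bestVal <- vr$fl$loss; bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= config$patience) break
      }
    }
    model@layers <- layers
    model@trained <- TRUE
    list(model = model,
         history = do.call(rbind, hist[!vapply(hist, is.null, logical(1))]))
  })
}

#' Predict the tumor/normal label of one image
#'
#' @param model a trained [ClassifierModel-class].
#' @param image a numeric matrix (resized internally via [prepareInput()]).
#' @return list with `label` (`"tumor"` or `"normal"`) and `prob` (named
#'   probabilities summing to 1).
#' @export
predictLabel <- function(model, image) {
  stopifnot(is(model, "ClassifierModel"))
  X <- clfBatch(model, list(image))
  fw <- nnForward(model@layers, X, model@inputSize, model@inputSize, 1L,
                  training = FALSE)
  p <- softmaxRows(fw$out)[1L, ]
  names(p) <- model@classes
  list(label = model@classes[which.max(p)], prob = p)
}

# checksum of all parameters of the backbone (excluding the head); used to
# verify the freezing contract
backboneChecksum <- function(model) {
  nl <- length(model@layers)
  sum(vapply(parameterList(model@layers[-nl]), sum, numeric(1)))
}
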