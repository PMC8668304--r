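#' Construct focal loss parameters
#'
#' The focal loss down-weights easy pixels by the factor
#' \eqn{(1-p_t)^\gamma}, addressing the heavy background/tumor class
#' imbalance of pixel classification: per contributing pixel the loss is
#' \eqn{-(1-p_t)^\gamma \, l_t \ln p_t}, with \eqn{p_t} the predicted
#' probability of the pixel's true class and \eqn{l_t} its class weight.
#'
#' @param gamma focusing exponent, >= 0 (default 10, the training default;
#'   see [trainingConfig()]). `gamma = 0` reduces the loss to weighted
#'   cross-entropy.
#' @param classWeights per-class weights, recycled to the number of classes.
#' @param ignoreLabel mask label excluded from the loss (default 255).
#' @return a [FocalLossParams-class].
#' @export
focalLossParams <- function(gamma = 10, classWeights = 1, ignoreLabel = 255L) {
  obj <- new("FocalLossParams", gamma = gamma,
             classWeights = as.numeric(classWeights),
             ignoreLabel = as.integer(ignoreLabel))
  validObject(obj)
  obj
}

#' Construct a segmentation training configuration
#'
#' Defaults follow the reference recipe: Adam with initial learning rate
#' 0.001, minibatch size 30, at most 20 epochs, shuffling each epoch, Glorot
#' (Xavier) weight initialization, focal focusing value 10, and early
#' stopping once the validation loss has exceeded its running minimum on 10
#' consecutive checks.
#'
#' @param learningRate Adam learning rate (> 0).
#' @param minibatchSize images per minibatch (>= 1).
#' @param maxEpochs maximum training epochs (>= 1).
#' @param shuffleEachEpoch reshuffle the training order every epoch.
#' @param focalGamma focal focusing exponent (default 10; `2` is a tamer
#'   alternative if training is unstable).
#' @param seed integer seed controlling initialization, shuffling and dropout.
#' @param validationFraction fraction of the data held out for validation
#'   when no explicit validation set is supplied.
#' @param patience consecutive validation checks above the running-minimum
#'   loss before early stopping.
#' @return a [TrainingConfig-class].
#' @export
trainingConfig <- function(learningRate = 0.001, minibatchSize = 30L,
                           maxEpochs = 20L, shuffleEachEpoch = TRUE,
                           focalGamma = 10, seed = 1L,
                           validationFraction = 0.1, patience = 10L) {
  obj <- new("TrainingConfig", learningRate = learningRate,
             minibatchSize = as.integer(minibatchSize),
             maxEpochs = as.integer(maxEpochs),
             shuffleEachEpoch = isTRUE(shuffleEachEpoch),
             focalGamma = focalGamma, seed = as.integer(seed),
             validationFraction = validationFraction,
             patience = as.integer(patience))
  validObject(obj)
  obj
}

#' Build the fully convolutional segmentation network
#'
#' Encoder: three blocks of (3x3 convolution with 64 filters, stride 1,
#' padding 1; batch normalization; ReLU), with a 2x2 max-pool after the
#' first and second blocks. The pool is applied with stride 2 (true
#' downsampling), so the encoder reduces resolution by a factor of 4.
#' Decoder: one 2x stride-2 transposed convolution per pooling stage (with a
#' ReLU after the first) followed by a 1x1 convolution onto `nClasses`
#' channels; per-pixel softmax yields class probabilities at input
#' resolution. Weights are Glorot-initialized from `seed`.
#'
#' @param nClasses number of output classes (>= 2; default 2, tumor vs
#'   background).
#' @param inChannels input channel count (default 1).
#' @param seed integer seed for weight initialization.
#' @param filters encoder filter count per convolution (default 64).
#' @param decoderFilters filter counts of the two transposed convolutions.
#' @return an untrained [FcnnModel-class].
#' @examples
#' m <- buildFcnn(seed = 1)
#' m
#' @export
buildFcnn <- function(nClasses = 2L, inChannels = 1L, seed = 1L,
                      filters = 64L, decoderFilters = c(32L, 16L)) {
  if (nClasses < 2L) stop("'nClasses' must be >= 2", call. = FALSE)
  layers <- withSeed(seed, list(
    layerConv(3L, inChannels, filters), layerBN(filters), layerReLU(),
    layerPool(),
    layerConv(3L, filters, filters), layerBN(filters), layerReLU(),
    layerPool(),
    layerConv(3L, filters, filters), layerBN(filters), layerReLU(),
    layerTConv(filters, decoderFilters[1]), layerReLU(),
    layerTConv(decoderFilters[1], decoderFilters[2]),
    layerConv(1L, decoderFilters[2], nClasses)
  ))
  new("FcnnModel", layers = layers, nClasses = as.integer(nClasses),
      inChannels = as.integer(inChannels), poolFactor = 4L,
      trained = FALSE, config = NULL)
}

checkFcnnInput <- function(model, h, w) {
  f <- model@poolFactor
  if (h %% f != 0L || w %% f != 0L)
    stop("input dimensions (", h, "x", w, ") must be divisible by the ",
         "network's pooling factor ", f, call. = FALSE)
}

#' Focal loss of a probability map against a target mask
#'
#' @param probMap an H x W x K array of per-pixel class probabilities (each
#'   pixel's probabilities summing to 1), or an H x W matrix of tumor-class
#'   probabilities for the binary case.
#' @param target an H x W integer mask with labels `0..K-1`; pixels equal to
#'   `params@ignoreLabel` contribute nothing.
#' @param params a [FocalLossParams-class].
#' @return the mean per-pixel focal loss over contributing pixels.
#' @examples
#' p <- array(c(0.1, 0.9), dim = c(1, 1, 2))
#' focalLoss(p, matrix(1L, 1, 1), focalLossParams(gamma = 2, classWeights = 1))
#' # 0.01 * -log(0.9)
#' @export
focalLoss <- function(probMap, target, params = focalLossParams()) {
  stopifnot(is(params, "FocalLossParams"))
  if (is.matrix(probMap))
    probMap <- array(c(1 - probMap, probMap),
                     dim = c(nrow(probMap), ncol(probMap), 2L))
  d <- dim(probMap)
  if (length(d) != 3L)
    stop("'probMap' must be an H x W x K array", call. = FALSE)
  if (!is.matrix(target) || nrow(target) != d[1] || ncol(target) != d[2])
    stop("'target' must be an H x W mask aligned with 'probMap'",
         call. = FALSE)
  K <- d[3]
  P <- matrix(probMap, d[1] * d[2], K)
  tgt <- as.integer(target)
  tgt[tgt == params@ignoreLabel] <- NA_integer_
  if (any(!is.na(tgt) & (tgt < 0L | tgt >= K)))
    stop("'target' labels must lie in 0..K-1 (or the ignore label)",
         call. = FALSE)
  keep <- !is.na(tgt)
  if (!any(keep))
    stop("degenerate batch: no pixels contribute to the loss", call. = FALSE)
  w <- rep_len(params@classWeights, K)
  pt <- pmax(P[cbind(which(keep), tgt[keep] + 1L)], 1e-7)
  mean(w[tgt[keep] + 1L] * pmax(1 - pt, 0)^params@gamma * (-log(pt)))
}

# stack a list of images into the (N*P, 1) activation layout, applying
# per-image z-score normalization (the network-input normalization)
stackImages <- function(imgs, normalize = TRUE) {
  cols <- lapply(imgs, function(im) {
    if (normalize) im <- normalizeZscore(im)$image
    as.vector(im)
  })
  matrix(unlist(cols), ncol = 1L)
}

stackTargets <- function(msks, ignoreLabel = 255L) {
  tgt <- unlist(lapply(msks, as.integer))
  tgt[tgt == ignoreLabel] <- NA_integer_
  tgt
}

segForwardLoss <- function(layers, imgs, msks, gamma, weights, n, h, w,
                           training) {
  X <- stackImages(imgs)
  fw <- nnForward(layers, X, h, w, n, training = training)
  tgt <- stackTargets(msks)
  fl <- focalFromLogits(fw$out, tgt, gamma, weights)
  pred <- max.col(fl$prob, ties.method = "first") - 1L
  list(fw = fw, fl = fl, acc = mean(pred == tgt, na.rm = TRUE))
}

#' Train the segmentation network
#'
#' Minibatch Adam on the focal loss. Class weights default to inverse class
#' frequency computed on the training split (normalized to mean 1). Each
#' epoch records training and validation loss and pixel accuracy; training
#' stops early once the validation loss has exceeded its running minimum on
#' `config@patience` consecutive epochs. The run is fully reproducible from
#' `config@seed`. Inputs are per-image z-score normalized internally;
#' [predictMask()] applies the same normalization.
#'
#' @param model an untrained [FcnnModel-class] (see [buildFcnn()]).
#' @param data a [PhantomDataset-class] with pixel masks (images should
#'   already be preprocessed/skull-stripped as desired).
#' @param config a [TrainingConfig-class].
#' @param valData optional explicit validation [PhantomDataset-class]; if
#'   missing, `config@validationFraction` of `data` is held out.
#' @param classWeights optional explicit per-class loss weights.
#' @return list with `model` (trained [FcnnModel-class]) and `history`
#'   (data.frame with epoch, train_loss, val_loss, train_acc, val_acc).
#' @export
trainSegmenter <- function(model, data, config = trainingConfig(),
                           valData = NULL, classWeights = NULL) {
  stopifnot(is(model, "FcnnModel"), is(config, "TrainingConfig"))
  if (!is(data, "PhantomDataset") || length(data) == 0L)
    stop("'data' must be a non-empty PhantomDataset", call. = FALSE)
  h <- nrow(data@images[[1]]); w <- ncol(data@images[[1]])
  checkFcnnInput(model, h, w)

  withSeed(config@seed, {
    if (is.null(valData)) {
      nVal <- max(1L, round(length(data) * config@validationFraction))
      vi <- sample(length(data), nVal)
      valData <- data[vi]
      data <- data[-vi]
    }
    if (is.null(classWeights)) {
      tab <- numeric(model@nClasses)
      for (m in data@masks) {
        v <- as.integer(m); v <- v[v != 255L]
        tab <- tab + tabulate(v + 1L, nbins = model@nClasses)
      }
      classWeights <- sum(tab) / (model@nClasses * pmax(tab, 1))
      classWeights <- classWeights / mean(classWeights)
    }
    layers <- model@layers
    state <- adamInit(layers)
    nTrain <- length(data)
    bs <- min(config@minibatchSize, nTrain)
    hist <- vector("list", config@maxEpochs)
    bestVal <- Inf
    bad <- 0L
    t <- 0L
    for (epoch in seq_len(config@maxEpochs)) {
      ord <- if (config@shuffleEachEpoch) sample(nTrain) else seq_len(nTrain)
      epLoss <- 0; epAcc <- 0; nb <- 0L
      for (start in seq(1L, nTrain, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, nTrain)]
        r <- segForwardLoss(layers, data@images[idx], data@masks[idx],
                            config@focalGamma, classWeights,
                            length(idx), h, w, training = TRUE)
        layers <- r$fw$layers
        bw <- nnBackward(layers, r$fw$caches, r$fl$dZ)
        t <- t + 1L
        up <- adamStep(layers, bw$grads, state, config@learningRate, t)
        layers <- up$layers
        state <- up$state
        epLoss <- epLoss + r$fl$loss
        epAcc <- epAcc + r$acc
        nb <- nb + 1L
      }
      vr <- segForwardLoss(layers, valData@images, valData@masks,
                           config@focalGamma, classWeights,
                           length(valData), h, w, training = FALSE)
      hist[[epoch]] <- data.frame(
        epoch = epoch, train_loss = epLoss / nb, val_loss = vr$fl$loss,
        train_acc = epAcc / nb, val_acc = vr$acc)
      if (vr$fl$loss < bestVal) {
        bestVal <- vr$fl$loss
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= config@patience) break
      }
    }
    model@layers <- layers
    model@trained <- TRUE
    model@config <- config
    list(model = model, history = do.call(rbind, hist[!vapply(hist, is.null,
                                                              logical(1))]))
  })
}

#' Predict a tumor probability map and mask for one image
#'
#' Runs the trained network on a single image (per-image z-score normalized,
#' matching training), returning the per-pixel class probability map and the
#' argmax label mask.
#'
#' @param model a trained [FcnnModel-class].
#' @param image a numeric matrix whose dimensions are divisible by the
#'   network's pooling factor.
#' @return list with `prob` (H x W x K array, per-pixel probabilities
#'   summing to 1) and `mask` (H x W integer argmax labels, `0..K-1`).
#' @export
predictMask <- function(model, image) {
  stopifnot(is(model, "FcnnModel"))
  assertImage2D(image)
  h <- nrow(image); w <- ncol(image)
  checkFcnnInput(model, h, w)
  X <- stackImages(list(image))
  fw <- nnForward(model@layers, X, h, w, 1L, training = FALSE)
  P <- softmaxRows(fw$out)
  prob <- array(P, dim = c(h, w, model@nClasses))
  mask <- matrix(max.col(P, ties.method = "first") - 1L, h, w)
  list(prob = prob, mask = mask)
}
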