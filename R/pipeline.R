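#' Default pipeline configuration
#'
#' Nested configuration for the five-stage workflow at desk scale: 200
#' 64x64 phantoms (Gaussian noise sigma 0.05, 20 subjects, half tumor),
#' preprocessing with median filter and edge enhancement, skull stripping,
#' FCNN segmentation training, probability-map postprocessing, transfer
#' classification with the scratch inception backbone, and 70/10/20
#' evaluation. The single global `seed` fans out to independent per-stage
#' seeds so any stage can be rerun in isolation reproducibly.
#'
#' @param seed global integer seed.
#' @param outDir optional output directory for artifacts (masks, metrics,
#'   histories, manifest); `NULL` keeps everything in memory.
#' @param ... named overrides merged into the defaults, e.g.
#'   `phantom = list(nImages = 100)`.
#' @return a nested list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(seed = 1L, outDir = NULL, ...) {
  cfg <- list(
    seed = as.integer(seed),
    outDir = outDir,
    phantom = list(nImages = 200L, tumorFraction = 0.5, nSubjects = 20L,
                   height = 64L, width = 64L, tumorRadiusPx = 8,
                   noiseSigma = 0.05, noiseModel = "gaussian"),
    preprocess = list(enabled = TRUE, median = TRUE, edgeEnhance = TRUE),
    skullstrip = list(enabled = TRUE, openingRadius = 2L, closingRadius = 3L,
                      connectivity = 8L),
    segnet = list(enabled = TRUE, filters = 64L, focalGamma = 10,
                  learningRate = 0.001, minibatchSize = 30L, maxEpochs = 20L),
    postprocess = list(enabled = TRUE, tau = 0.5, minRegionPx = 12L,
                       connectivity = 8L),
    classify = list(enabled = TRUE, inputSize = 32L, epochs = 15L,
                    batchSize = 30L, learningRate = 0.001),
    evaluate = list(fractions = c(0.7, 0.1, 0.2))
  )
  over <- list(...)
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      utils::modifyList(cfg[[nm]], over[[nm]]) else over[[nm]]
  }
  structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [pipelineConfig()].
#' @return a `"PipelineConfig"` list.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipelineConfig,
          c(list(seed = if (is.null(y$seed)) 1L else y$seed,
                 outDir = y$outDir),
            y[setdiff(names(y), c("seed", "outDir"))]))
}

#' Run the five-stage pipeline end to end
#'
#' Generate -> preprocess -> skull strip -> train/segment -> postprocess ->
#' train/classify -> evaluate. Individual stages can be disabled via their
#' `enabled` flag (segmentation then evaluates raw argmax masks when
#' postprocessing is off, and classification consumes whatever the last
#' enabled image stage produced). When `config$outDir` is set, metrics,
#' histories, per-image predictions and a manifest capturing the fully
#' resolved configuration and seed are written there.
#'
#' @param config a [pipelineConfig()].
#' @param quiet suppress stage progress messages.
#' @return invisibly, a list with `segMetrics` and `clfMetrics`
#'   ([MetricsReport-class] on the held-out test set), `segDice` (per-test-
#'   image Dice, percent), `segHistory`, `clfHistory`, `split`, and `config`.
#' @export
runPipeline <- function(config = pipelineConfig(), quiet = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  stageSay <- function(stage) say("[%s] %s", format(round(difftime(
    Sys.time(), t0, units = "secs"), 1)), stage)

  ph <- config$phantom
  stageSay(sprintf("generating %d phantoms (%dx%d, sigma %.3f)",
                   ph$nImages, ph$height, ph$width, ph$noiseSigma))
  base <- phantomSpec(height = ph$height, width = ph$width,
                      tumor = list(radiusPx = ph$tumorRadiusPx),
                      noise = list(model = ph$noiseModel,
                                   sigma = ph$noiseSigma))
  ds <- generateDataset(ph$nImages, ph$tumorFraction, ph$nSubjects,
                        baseSpec = base,
                        seed = deriveSeed(config$seed, "phantom"))

  imgs <- ds@images
  if (isTRUE(config$preprocess$enabled)) {
    stageSay("preprocessing (median filter + edge enhancement)")
    imgs <- lapply(imgs, preprocessImage,
                   median = config$preprocess$median,
                   edgeEnhance = config$preprocess$edgeEnhance)
  }
  if (isTRUE(config$skullstrip$enabled)) {
    stageSay("skull stripping")
    imgs <- lapply(imgs, function(im)
      stripSkull(im, openingRadius = config$skullstrip$openingRadius,
                 closingRadius = config$skullstrip$closingRadius,
                 connectivity = config$skullstrip$connectivity)$image)
  }
  work <- ds
  work@images <- imgs

  split <- splitDataset(length(work), seed = deriveSeed(config$seed, "split"),
                        fractions = config$evaluate$fractions)
  trainSet <- work[split@trainIdx]
  valSet <- work[split@valIdx]
  testSet <- work[split@testIdx]

  segRes <- NULL; segDice <- NULL; segMetrics <- NULL; predMasks <- NULL
  if (isTRUE(config$segnet$enabled)) {
    stageSay("training segmentation network")
    sc <- config$segnet
    model <- buildFcnn(filters = sc$filters,
                       seed = deriveSeed(config$seed, "segnet-init"))
    tc <- trainingConfig(learningRate = sc$learningRate,
                         minibatchSize = sc$minibatchSize,
                         maxEpochs = sc$maxEpochs, focalGamma = sc$focalGamma,
                         seed = deriveSeed(config$seed, "segnet-train"))
    segRes <- trainSegmenter(model, trainSet, tc, valData = valSet)
    stageSay("segmenting test images")
    preds <- lapply(testSet@images, predictMask, model = segRes$model)
    predMasks <- lapply(preds, function(p) {
      if (isTRUE(config$postprocess$enabled))
        postprocessMask(p$prob[, , 2L], tau = config$postprocess$tau,
                        minRegionPx = config$postprocess$minRegionPx,
                        connectivity = config$postprocess$connectivity)
      else p$mask
    })
    cms <- Map(segmentationConfusion, predMasks, testSet@masks)
    segDice <- unlist(Map(diceScore, predMasks, testSet@masks))
    pooled <- new("ConfusionMatrix",
                  TP = sum(vapply(cms, slot, numeric(1), "TP")),
                  FP = sum(vapply(cms, slot, numeric(1), "FP")),
                  FN = sum(vapply(cms, slot, numeric(1), "FN")),
                  TN = sum(vapply(cms, slot, numeric(1), "TN")),
                  positive = "1")
    segMetrics <- computeMetrics(pooled)
  }

  clfRes <- NULL; clfMetrics <- NULL; clfPred <- NULL
  if (isTRUE(config$classify$enabled)) {
    stageSay("training classifier")
    cc <- config$classify
    clf <- adaptBackbone("mini_inception_scratch",
                         seed = deriveSeed(config$seed, "clf-init"))
    cfg2 <- transferConfig(fineTuneLr = cc$learningRate, epochs = cc$epochs,
                           batchSize = cc$batchSize,
                           seed = deriveSeed(config$seed, "clf-train"))
    clfRes <- trainClassifier(clf, trainSet, cfg2, valData = valSet)
    preds <- lapply(testSet@images, predictLabel, model = clfRes$model)
    clfPred <- data.frame(
      predicted = vapply(preds, `[[`, character(1), "label"),
      p_normal = vapply(preds, function(p) p$prob[["normal"]], numeric(1)),
      p_tumor = vapply(preds, function(p) p$prob[["tumor"]], numeric(1)))
    clfMetrics <- computeMetrics(
      binaryConfusion(testSet@labels, clfPred$predicted, positive = "tumor"))
  }

  out <- list(segMetrics = segMetrics, clfMetrics = clfMetrics,
              segDice = segDice, predMasks = predMasks,
              segHistory = if (!is.null(segRes)) segRes$history,
              clfHistory = if (!is.null(clfRes)) clfRes$history,
              split = split, config = config)

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    writeRunArtifacts(out, testSet, clfPred, config)
  }
  stageSay("done")
  invisible(out)
}

#' Save or load a trained model checkpoint
#'
#' The model is written in R's native serialized form (`.rds`) together
#' with a JSON sidecar describing the architecture and, when available, the
#' training configuration, so a checkpoint is self-describing without being
#' deserialized.
#'
#' @param model an [FcnnModel-class] or [ClassifierModel-class].
#' @param path destination `.rds` path; the sidecar is written next to it
#'   as `<path>.json`.
#' @return `path`, invisibly.
#' @export
writeModel <- function(model, path) {
  stopifnot(is(model, "FcnnModel") || is(model, "ClassifierModel"))
  saveRDS(model, path)
  side <- if (is(model, "FcnnModel")) {
    list(kind = "FcnnModel", nClasses = model@nClasses,
         inChannels = model@inChannels, poolFactor = model@poolFactor,
         trained = model@trained,
         layers = vapply(model@layers, `[[`, character(1), "type"),
         config = if (!is.null(model@config)) list(
           learningRate = model@config@learningRate,
           minibatchSize = model@config@minibatchSize,
           maxEpochs = model@config@maxEpochs,
           focalGamma = model@config@focalGamma,
           seed = model@config@seed))
  } else {
    list(kind = "ClassifierModel", inputSize = model@inputSize,
         inChannels = model@inChannels, frozen = model@frozen,
         classes = model@classes, trained = model@trained,
         layers = vapply(model@layers, `[[`, character(1), "type"))
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  m <- readRDS(path)
  stopifnot(is(m, "FcnnModel") || is(m, "ClassifierModel"))
  m
}

writeRunArtifacts <- function(out, testSet, clfPred, config) {
  od <- config$outDir
  manifest <- list(seed = config$seed,
                   config = unclass(config),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  mrow <- function(m) if (is.null(m)) NULL else as.vector(m)
  metr <- rbind(segmentation = mrow(out$segMetrics),
                classification = mrow(out$clfMetrics))
  if (!is.null(metr)) {
    write.csv(data.frame(task = rownames(metr), metr, row.names = NULL),
              file.path(od, "metrics.csv"), row.names = FALSE)
    jsonlite::write_json(apply(metr, 1L, as.list),
                         file.path(od, "metrics.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  if (!is.null(out$segHistory))
    write.csv(out$segHistory, file.path(od, "seg_history.csv"),
              row.names = FALSE)
  if (!is.null(out$clfHistory))
    write.csv(out$clfHistory, file.path(od, "clf_history.csv"),
              row.names = FALSE)
  if (!is.null(clfPred))
    write.csv(cbind(data.frame(index = out$split@testIdx,
                               label = testSet@labels), clfPred),
              file.path(od, "predictions.csv"), row.names = FALSE)
  if (!is.null(out$predMasks)) {
    md <- file.path(od, "masks")
    dir.create(md, showWarnings = FALSE)
    for (i in seq_along(out$predMasks))
      writeMaskImage(out$predMasks[[i]],
                     file.path(md, sprintf("pred_%04d.png", i)))
  }
  invisible(od)
}
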