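#' Construct a phantom specification
#'
#' Builds a [PhantomSpec-class] describing one synthetic axial brain slice.
#' Defaults emulate the geometry of 240x240 MR slices: a bright skull ring
#' near the image border, a dark CSF gap, mildly textured brain tissue, and
#' (optionally) a hyperintense tumor disk whose rim fades over `softnessPx`.
#' The modality tag modulates the intensity profile only (FLAIR/T1CE-style
#' lesions are brighter); it is metadata, not an extra channel.
#'
#' @param height,width image dimensions in pixels (>= 32).
#' @param skullRing list overriding any of `innerRadiusFrac` (default 0.82),
#'   `thicknessPx` (6), `intensity` (0.95), `gapPx` (3).
#' @param brainTissue list overriding `meanIntensity` (0.40), `textureSd` (0.05).
#' @param tumor list overriding `present` (TRUE), `center` (image center),
#'   `radiusPx` (`round(min(height, width)/12)`, i.e. 20 at 240),
#'   `intensity` (0.80), `softnessPx` (2).
#' @param noise list overriding `model` ("gaussian" or "rician") and
#'   `sigma` (0.05).
#' @param modalityTag one of "T1", "T2", "T1CE", "FLAIR".
#' @param subjectId opaque subject identifier.
#' @param seed integer seed; the phantom is a pure function of (spec, seed).
#' @return a validated [PhantomSpec-class].
#' @examples
#' spec <- phantomSpec(height = 64, width = 64, seed = 1)
#' out <- generatePhantom(spec)
#' out$label
#' @export
phantomSpec <- function(height = 240L, width = 240L,
                        skullRing = list(), brainTissue = list(),
                        tumor = list(), noise = list(),
                        modalityTag = "T1", subjectId = "S1", seed = 1L) {
  ring <- utils::modifyList(
    list(innerRadiusFrac = 0.82, thicknessPx = 6, intensity = 0.95, gapPx = 3),
    skullRing)
  tissue <- utils::modifyList(
    list(meanIntensity = 0.40, textureSd = 0.05), brainTissue)
  tum <- utils::modifyList(
    list(present = TRUE, center = c(NA_real_, NA_real_),
         radiusPx = round(min(height, width) / 12), intensity = 0.80,
         softnessPx = 2),
    tumor)
  nz <- utils::modifyList(list(model = "gaussian", sigma = 0.05), noise)
  new("PhantomSpec", height = as.integer(height), width = as.integer(width),
      skullRing = ring, brainTissue = tissue, tumor = tum, noise = nz,
      modalityTag = modalityTag, subjectId = subjectId,
      seed = as.integer(seed))
}

# modality-specific multiplier on lesion contrast; FLAIR/T1CE lesions brighter
modalityLesionGain <- function(tag) {
  switch(tag, T1 = 1.0, T2 = 1.05, T1CE = 1.12, FLAIR = 1.15)
}

#' Generate one synthetic brain phantom
#'
#' Renders the image described by a [PhantomSpec-class] together with its
#' pixel-level tumor mask and image-level label. Intensities are clipped to
#' \[0, 1\]. Rician noise is the magnitude of (signal + g1, g2) with
#' independent zero-mean Gaussians; Gaussian noise is plain additive.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with elements `image` (numeric matrix), `mask` (integer
#'   matrix, 1 on tumor pixels), `label` (`"tumor"` or `"normal"`), and
#'   `brainMask` (integer matrix, 1 on the true brain-tissue disk — ground
#'   truth for skull stripping).
#' @details The tumor disk must lie strictly inside the brain-tissue region;
#'   a placement that would overlap the CSF gap, skull ring or background
#'   raises an error.
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  h <- spec@height; w <- spec@width
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  rBrain <- spec@skullRing$innerRadiusFrac * min(h, w) / 2
  gap <- spec@skullRing$gapPx
  thick <- spec@skullRing$thicknessPx

  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  d <- sqrt((rr - cy)^2 + (cc - cx)^2)

  brain <- d <= rBrain
  ring <- d > rBrain + gap & d <= rBrain + gap + thick

  tum <- spec@tumor
  mask <- matrix(0L, h, w)
  if (isTRUE(tum$present)) {
    ctr <- tum$center
    if (any(is.na(ctr))) ctr <- c(cy, cx)
    reach <- sqrt((ctr[1] - cy)^2 + (ctr[2] - cx)^2) +
      tum$radiusPx + tum$softnessPx
    if (reach > rBrain - 1)
      stop("tumor placement error: disk (center ", paste(round(ctr, 1), collapse = ","),
           ", radius ", tum$radiusPx, " + softness ", tum$softnessPx,
           ") does not fit strictly inside the brain region (radius ",
           round(rBrain, 1), ")", call. = FALSE)
    dt <- sqrt((rr - ctr[1])^2 + (cc - ctr[2])^2)
    mask[dt <= tum$radiusPx] <- 1L
  }

  img <- withSeed(spec@seed, {
    base <- matrix(0, h, w)
    tex <- matrix(rnorm(h * w, 0, spec@brainTissue$textureSd), h, w)
    base[brain] <- spec@brainTissue$meanIntensity + tex[brain]
    base[ring] <- spec@skullRing$intensity
    if (isTRUE(tum$present)) {
      ctr <- tum$center
      if (any(is.na(ctr))) ctr <- c(cy, cx)
      dt <- sqrt((rr - ctr[1])^2 + (cc - ctr[2])^2)
      gain <- modalityLesionGain(spec@modalityTag)
      lesion <- min(1, tum$intensity * gain)
      # soft rim: full lesion intensity inside the disk, linear fade over softnessPx
      s <- pmax(0, pmin(1, 1 - (dt - tum$radiusPx) / max(tum$softnessPx, 1e-9)))
      s[dt <= tum$radiusPx] <- 1
      base <- base * (1 - s) + lesion * s
      base[!brain] <- 0
      base[ring] <- spec@skullRing$intensity
    }
    sig <- spec@noise$sigma
    if (sig > 0) {
      if (spec@noise$model == "gaussian") {
        base <- base + matrix(rnorm(h * w, 0, sig), h, w)
      } else {
        g1 <- matrix(rnorm(h * w, 0, sig), h, w)
        g2 <- matrix(rnorm(h * w, 0, sig), h, w)
        base <- sqrt((base + g1)^2 + g2^2)
      }
    }
    pmin(pmax(base, 0), 1)
  })

  list(image = img, mask = mask,
       label = if (any(mask == 1L)) "tumor" else "normal",
       brainMask = matrix(as.integer(brain), h, w))
}

#' Generate a seeded phantom dataset
#'
#' Produces `nImages` phantoms with exactly `round(nImages * tumorFraction)`
#' tumor-bearing images, subject identifiers partitioning the images into
#' `nSubjects` groups, modality tags cycling through T1/T2/T1CE/FLAIR, and
#' per-image parameters (tumor radius, center, intensity and tissue level)
#' jittered deterministically from `seed`.
#'
#' @param nImages number of images (> 0).
#' @param tumorFraction proportion of tumor-bearing images in \[0, 1\].
#' @param nSubjects number of distinct subjects (<= `nImages`).
#' @param baseSpec a [PhantomSpec-class] giving the nominal parameters.
#' @param seed integer seed for the whole dataset.
#' @return a [PhantomDataset-class].
#' @examples
#' ds <- generateDataset(10, 0.5, nSubjects = 3,
#'                       baseSpec = phantomSpec(64, 64), seed = 2)
#' table(imageLabels(ds))
#' @export
generateDataset <- function(nImages, tumorFraction = 0.5, nSubjects = 1L,
                            baseSpec = phantomSpec(), seed = 1L) {
  if (!is.numeric(nImages) || nImages <= 0)
    stop("'nImages' must be a positive count", call. = FALSE)
  if (tumorFraction < 0 || tumorFraction > 1)
    stop("'tumorFraction' must be in [0, 1]", call. = FALSE)
  if (nSubjects > nImages)
    stop("'nSubjects' must be <= 'nImages'", call. = FALSE)
  nImages <- as.integer(nImages)
  nTumor <- as.integer(round(nImages * tumorFraction))

  h <- baseSpec@height; w <- baseSpec@width
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  rBrain <- baseSpec@skullRing$innerRadiusFrac * min(h, w) / 2
  mods <- c("T1", "T2", "T1CE", "FLAIR")

  params <- withSeed(deriveSeed(seed, "phantom-dataset"), {
    isTumor <- sample(rep(c(TRUE, FALSE), c(nTumor, nImages - nTumor)))
    # subjects own contiguous blocks of the shuffled order => every subject
    # gets >= 1 image and sizes differ by <= 1
    subj <- sort(rep_len(seq_len(nSubjects), nImages))
    lapply(seq_len(nImages), function(i) {
      radius <- max(3, baseSpec@tumor$radiusPx * runif(1, 0.7, 1.3))
      maxOff <- max(0, rBrain - 1 - radius - baseSpec@tumor$softnessPx)
      ang <- runif(1, 0, 2 * pi)
      off <- runif(1, 0, 0.8 * maxOff)
      list(isTumor = isTumor[i],
           subject = sprintf("S%02d", subj[i]),
           modality = mods[(i - 1L) %% 4L + 1L],
           radius = radius,
           center = c(cy + off * sin(ang), cx + off * cos(ang)),
           intensity = baseSpec@tumor$intensity * runif(1, 0.92, 1.08),
           tissueMean = baseSpec@brainTissue$meanIntensity * runif(1, 0.92, 1.08),
           imgSeed = sample.int(2147483646L, 1))
    })
  })

  out <- lapply(params, function(p) {
    sp <- phantomSpec(
      height = h, width = w,
      skullRing = baseSpec@skullRing,
      brainTissue = utils::modifyList(baseSpec@brainTissue,
                                      list(meanIntensity = p$tissueMean)),
      tumor = utils::modifyList(baseSpec@tumor,
                                list(present = p$isTumor, center = p$center,
                                     radiusPx = p$radius,
                                     intensity = min(p$intensity, 0.98))),
      noise = baseSpec@noise, modalityTag = p$modality,
      subjectId = p$subject, seed = p$imgSeed)
    generatePhantom(sp)
  })

  new("PhantomDataset",
      images = lapply(out, `[[`, "image"),
      masks = lapply(out, `[[`, "mask"),
      labels = vapply(out, `[[`, character(1), "label"),
      subjectIds = vapply(params, `[[`, character(1), "subject"),
      modalityTags = vapply(params, `[[`, character(1), "modality"),
      seed = as.integer(seed))
}

#' Write a phantom dataset to disk
#'
#' Writes image/mask pairs as 8-bit PNG or float32 NIfTI plus a manifest CSV
#' with columns `image_path, mask_path, label, subject_id, modality, seed`.
#'
#' @param dataset a [PhantomDataset-class].
#' @param dir output directory (created if missing).
#' @param format `"png"` or `"nifti"`.
#' @return invisibly, the manifest as a data.frame.
#' @export
writeDataset <- function(dataset, dir, format = c("png", "nifti")) {
  format <- match.arg(format)
  stopifnot(is(dataset, "PhantomDataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "png") "png" else "nii.gz"
  n <- length(dataset@images)
  rows <- lapply(seq_len(n), function(i) {
    ip <- file.path(dir, sprintf("img_%04d.%s", i, ext))
    mp <- file.path(dir, sprintf("msk_%04d.%s", i, ext))
    writeImage2D(dataset@images[[i]], ip)
    writeMaskImage(dataset@masks[[i]], mp)
    data.frame(image_path = ip, mask_path = mp, label = dataset@labels[i],
               subject_id = dataset@subjectIds[i],
               modality = dataset@modalityTags[i], seed = dataset@seed)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
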