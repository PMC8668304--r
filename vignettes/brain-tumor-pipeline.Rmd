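---
title: "Methods: the BrainTumorSeg five-stage pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the BrainTumorSeg five-stage pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BrainTumorSeg)
```

# Overview

BrainTumorSeg detects brain tumors in 2-D MR slices with a five-stage
workflow: preprocessing, skull stripping, fully convolutional pixel
classification, probability-map postprocessing, and a transfer-learning
binary classifier. Every stage is seeded and testable at desk scale on
synthetic phantoms with known pixel-level ground truth, so no external
imaging data is needed to exercise or validate the code path end to end.

This vignette records the model, its assumptions, the tunable parameters,
and the numerical and design choices made where the design was genuinely
open.

# The synthetic phantom generator

`generatePhantom()` renders a brain-like axial slice on [0, 1] intensities:

* a bright **skull ring** (default intensity 0.95, thickness 6 px) whose
  inner radius is 0.82 of the half-image;
* a thin dark **CSF gap** (default 3 px) between ring and tissue — CSF is
  dark on T1-weighted images, and this gap is what makes
  intensity-plus-morphology skull stripping well-posed;
* **brain tissue** with mean 0.40 and Gaussian texture (sd 0.05);
* an optional hyperintense **tumor disk** (default intensity 0.80, radius
  `min(h, w)/12`, i.e. 20 px at the 240 x 240 reference size) with a rim
  that fades linearly over `softnessPx`; the disk must fit strictly inside
  the tissue region or generation fails with a placement error;
* additive **Gaussian** noise or **Rician** noise (the magnitude of the
  signal plus two independent Gaussians — the standard MR magnitude-noise
  model), default sigma 0.05.

Modality tags (T1/T2/T1CE/FLAIR) are metadata that scale lesion contrast
(T1CE/FLAIR lesions brighter by 12–15%); they are not co-registered
channels. `generateDataset()` draws per-image jitter (tumor radius
0.7–1.3x, random center within the allowed disk, ±8% intensity) from a
single seed, assigns subjects as contiguous blocks so every subject owns at
least one image, and produces exactly `round(n * tumorFraction)` tumor
images.

Phantoms capture the properties the pipeline relies on — ring/tissue/
lesion intensity ordering, spatial compactness of lesions, noise — but not
anatomy: no gyri, ventricles, partial-volume effects, bias fields, or
inter-modality registration. Passing tests therefore demonstrate that the
implementation is correct and the pipeline recovers known truth under its
own assumptions, not that the trained weights transfer to clinical data.

# Preprocessing

Grayscale conversion uses the 0.299/0.587/0.114 luminance weights. Noise
suppression is a 3 x 3 **median filter**; edges are then strengthened by
correlating the image with the high-pass mask

```
-1  2 -1
 0  0  0
 1 -2  1
```

and adding the response back to the image. Three choices here were open
and are fixed as follows:

* **Border policy**: edge replication for both filters. Zero padding would
  create an artificial dark rim that distorts the skull-ring geometry the
  stripper depends on.
* **Correlation, not convolution**: the mask is applied exactly as printed
  (no 180° flip), the convention of image-processing toolkits. The mask is
  asymmetric; whether it should be paired with its transpose
  (gradient-pair style) is unknowable from its printed form, so it is
  applied in the stated single orientation.
* **Clipping**: the enhanced image is clipped back to the declared range
  so downstream stages keep a [0, 1] contract.

`normalizeZscore()` standardizes an image to mean 0, variance 1 (population
sd) — the normalization applied to every network input. It is applied
**per image**: the slices here are independent, which makes per-image the
faithful desk-scale analogue of per-patient normalization. Constant images
raise an explicit degenerate-input error rather than dividing by zero.

# Skull stripping

No published procedure exists for this stage, so the whole algorithm is a
design decision, kept behind a small interface (`stripSkull()`) so a real
brain extractor can be substituted:

1. automatic global threshold from the intensity histogram. A two-class
   Otsu threshold fails here: a head slice is trimodal (background, tissue,
   bright skull/lesion) and the two-class criterion often cuts *above*
   tissue. The implementation maximizes three-class between-class variance
   over two thresholds (256 bins) and uses the **lower** threshold as the
   background/head cut;
2. binary opening (disc radius 2) to remove noise bridges;
3. keep the largest 8-connected component (the tissue disk; the detached
   ring is far smaller);
4. binary closing (disc radius 3) and hole filling, then zero out
   everything outside the mask.

The output mask is guaranteed a single component without holes; tumors lie
inside the tissue by construction and are never removed on clean phantoms.

# Segmentation network

`buildFcnn()` constructs the pixel classifier:

* encoder: 3 x (3 x 3 convolution, 64 filters, stride 1, zero padding 1 →
  batch normalization → ReLU), with a 2 x 2 max-pool after the first and
  second blocks;
* decoder: one 2x stride-2 transposed convolution per pooling stage (32
  then 16 filters, ReLU after the first), then a 1 x 1 convolution onto
  the class channels and a per-pixel softmax.

The reference recipe prints stride [1 1] for the 2 x 2 pool while also
describing the pool as downsampling and pairing it with upsampling
transpose layers; a stride-1 pool does not downsample, so the pool is
implemented with stride 2. Output resolution equals input resolution for
any input divisible by the pooling factor 4; other sizes raise an explicit
size error.

Training (`trainSegmenter()`) is minibatch Adam (learning rate 0.001,
batch 30, at most 20 epochs, reshuffled each epoch, Glorot initialization)
on the **focal loss**

$$L = -\frac{1}{M}\sum_{\text{pixels}} (1-p_t)^\gamma\, l_t \ln p_t,$$

with $p_t$ the predicted probability of the pixel's true class, $l_t$ a
class weight, and pixels carrying the ignore label (255) excluded from
both $M$ and the sum. Choices:

* **gamma defaults to 10**, the stated focusing value of the reference
  recipe. This is far above the 2 customary for focal losses and strongly
  suppresses gradients from well-classified pixels; it is configurable,
  and gamma = 2 is the recommended setting when training stalls.
* **class weights** default to inverse class frequency on the training
  split, normalized to mean 1 — the only operationalizable reading of
  "weights allocated by difficulty" for a two-class mask problem.
* probabilities are clamped at 1e-7 before the logarithm; the focal factor
  uses $(1-p_t)$ floored at 1e-12 so the $\gamma$ term stays finite at
  $p_t \to 1$.
* early stopping: training ends once validation loss has exceeded its
  running minimum on 10 consecutive epoch-end checks.
* batch-norm uses minibatch statistics in training and running statistics
  (momentum 0.1) at inference, the standard convention.

The engine itself is an im2col/BLAS implementation written for this
package (dense (N·H·W) x C activation matrices, cached gather indices,
analytic backprop through every layer); its gradients are verified against
numerical differentiation in the test suite to better than 1e-6.

# Postprocessing

`postprocessMask()` applies a single global threshold tau to the
tumor-class probability map and removes connected components smaller than
`minRegionPx`. The reference work states that values were chosen "after
numerous experiments" without printing them; the defaults here are tau =
0.5 (the argmax-equivalent cut for two classes) and, at the 240 x 240
reference scale, 100 px (scaled to 12 px for the 64 x 64 desk-scale runs,
preserving the area fraction). Both are exposed in every configuration and
recorded in run manifests. Removal never adds pixels, is idempotent, and
touches only the tumor class.

Connected components are labeled through an igraph adjacency-components
formulation supporting 4- and 8-connectivity (8 is the default
everywhere); tests cross-check it against an independent flood-fill
oracle.

# Classification

`adaptBackbone()` implements the transfer recipe — replace the final fully
connected layer with a fresh 2-way head (dropout 0.5 before it), optionally
freeze everything else — on a replaceable backbone. Tests and default runs
use `miniInception()`, a two-block inception-style network (parallel
1x1/3x3/5x5 convolutions, channel concatenation, global average pooling)
trained from scratch at 32 x 32, so no pretrained weights ever need to be
downloaded; an externally pretrained GoogleNet can be plugged in as a
`ClassifierModel` with 224 x 224 three-channel inputs via
`prepareInput(..., channels = 3)`. The classification loss is plain
cross-entropy: the focal loss exists to counter *pixel* class imbalance in
segmentation, which image-level labels do not suffer from. Classification
consumes preprocessed, skull-stripped images, matching the stage order of
the workflow diagram; this is configurable.

# Evaluation

`splitDataset()` rounds the train share (70%) and test share (20%) half
up and gives the remainder to validation — the unique convention
reproducing all three reference partitions (1425 → 998/142/285, 1675 →
1173/167/335, 2470 → 1729/247/494). A small epsilon absorbs binary
floating-point error (0.7 · 1425 is 997.4999… in doubles).

Metrics follow the standard confusion-matrix formulas, reported as
percentages; zero-denominator metrics are NaN with a warning, never a
silent 0 or 100. Per-image Dice uses the both-empty convention: an image
with no true tumor and no predicted tumor scores 100 (a correct negative),
not 0 — without this convention a mean over a half-normal test set is
bounded near 50 regardless of segmentation quality. Aggregation over folds
reports mean ± population standard deviation.

Record-wise cross-validation stratifies by class (per-fold class counts
within ±1); subject-wise cross-validation assigns whole subjects greedily,
largest first, to the smallest fold, so no subject ever spans folds and
fold sizes are balanced up to the largest subject.

# Desk-scale problem sizes

The shipped configurations and the reproduction script run at sizes chosen
to keep a full pipeline execution in minutes on one CPU while leaving the
learning problem non-trivial: 200 phantoms of 64 x 64 px (noise sigma
0.05, tumor radius 8 ± 30% jitter, 20 subjects, half tumor-bearing) for
segmentation, and 100 easy phantoms (32 x 32 inputs, sigma 0.02) for
classification. The architecture is size-agnostic — the same code builds
the 240 x 240 network — and `pipelineConfig()` exposes all of these knobs.

# Known limitations

* Phantoms are geometrically idealized; results on them bound nothing
  about clinical MRI performance.
* The FCNN engine is CPU-only and dense; it is adequate for desk-scale
  images, not for BRATS-scale training.
* gamma = 10 with inverse-frequency weights converges noticeably more
  slowly than gamma = 2 on easy phantoms; both are exposed.
* Skull stripping assumes a single connected head with a ring brighter
  than tissue and a dark gap between them; atlas-based extraction is out
  of scope.
* 2-D slices only; no 3-D volumes, no multi-channel co-registered
  modalities, no intra-tumor substructure (whole-tumor binary masks only).
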