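---
title: "Classifying whole-body bone-scan scintigrams: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying whole-body bone-scan scintigrams: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Whole-body bone scintigraphy surveys skeletal metastases by imaging the
uptake of a bone-seeking radiopharmaceutical (99mTc-MDP). Each study yields
two 256 x 1024 planar projections — an anterior and a posterior view — whose
pixels are 16-bit radiotracer counts. Scans are sensitive but unspecific:
benign processes, normal trabecular bone and tracer pooling in the bladder
or at the injection site all produce hotspots. `scintimet` implements a
complete pipeline for classifying such studies into three classes — no
metastasis (`NoMet`), adenocarcinoma-caused metastasis (`ADMet`) and
non-adenocarcinoma lung-cancer metastasis (`nADMet`) — together with a
synthetic phantom generator so every stage can be exercised and tested
without clinical data.

## View aggregation

Lesion uptake differs between the two views, so the pipeline fuses them
before classification. The posterior view is mirrored around its central
vertical line (the posterior projection is mirror-imaged relative to the
anterior), the two body regions are aligned, and the images are added
pixel-wise. Alignment uses four *critical points*: the first and last rows
and columns containing uptake above a threshold. We anchor the top-left
critical corner of the mirrored posterior onto the anterior's and translate
by whole pixels only — no rescaling or rotation — because translation
preserves count statistics exactly; pixels shifted out of bounds are
dropped and vacated pixels zero-filled. Where the two body extents differ
the alignment is therefore top-left anchored and the longer extent simply
runs past the shorter one; we chose this minimal interpretation over any
rescaling because a resampling step would change the count distribution the
network later normalises over.

The uptake threshold defaults to 0 (any recorded count marks the body),
since counts outside the patient silhouette are zero in practice; it is a
parameter of every alignment entry point. Addition is carried out in double
precision and the composite is *not* clipped back to 16 bits: a co-located
lesion should be "excited" — its excess counts above background sum across
views — and the network normalises its inputs anyway.

## Augmentation

Dataset expansion uses bounded parametric variation only: a rotation by an
angle drawn uniformly from $[0, r_T]$ degrees about the image centre, in a
uniformly random direction, and/or an integer translation drawn uniformly
from $[0, t_T]$ pixels along a random axis with random sign. The bounds
default to $r_T = 3$ degrees and $t_T = 3$ pixels — the magnitudes of the
worked examples for this image format — and are configurable. Rotation uses
bilinear interpolation (via EBImage) with any undershoot clamped at zero so
count images stay non-negative; translations are exact integer shifts with
zero fill. Augmented records inherit the source study's patient identifier,
which is what lets the splitter keep every derivative on the same side as
its source.

Augmentation can act at two stages: on the per-view images (with one shared
transform per study, keeping the two views anatomically consistent) or on
the already-fused composite. The composite stage is the default — it is
simpler and order-insensitive, and a rigid transform commutes with
pixel-wise addition up to interpolation error — while the view stage is
available through `stage = "view"`.

## The classifier

The network is a residual convolutional classifier: a 7x7/64 stride-2 stem
convolution with batch normalization and 3x3 stride-2 max pooling, four
stages of residual blocks with channel widths (64, 128, 256, 512), global
average pooling, and a fully-connected softmax head. Each block holds two
3x3 convolutions, each followed by batch normalization and a rectifier. The
first block of stages 2–4 uses stride 2 (the standard residual-network
convention; the stage table itself does not fix stride placement), which
yields a total downsampling of 32x and a 32x8 pre-GAP map for 1024x256
inputs. Counting convolutional and fully-connected layers only — not
shortcut projections, normalization, pooling, or layers inside the
attention module — block counts (2,3,5,2) give the 26-layer flagship and
(2,2,2,2)/(3,4,6,3) give 18- and 34-layer variants, consistent with
residual-network naming.

### Hybrid attention

Each block carries a hybrid attention module with two cascaded parts.
*Channel* attention pools the feature map spatially by mean and by maximum,
passes both channel descriptors through one shared bottleneck MLP
(channels → channels/r → channels, rectified in the middle), sums the
results and applies the logistic sigmoid. *Spatial* attention pools across
channels by mean and maximum, convolves the two resulting planes with a
single k x k filter (same padding) and applies the sigmoid. Defaults are
r = 16 and k = 7, the standard settings of the convolutional block
attention design this follows; sharing the MLP between the two pooled paths
follows the same design. All weights therefore lie strictly in (0, 1):
attention only attenuates.

Two composition conventions exist for the final products. The strict form
multiplies the *original* map by both weight sets,
$M = f_S(f_C(F) \otimes F) \otimes F$; the conventional cascaded form
refines progressively, $M = f_S(F') \otimes F'$ with
$F' = f_C(F) \otimes F$. Both are implemented; `strict_eq2 = TRUE` (the
default) selects the first, and the backward pass supports both. Placement
relative to the residual sum is configurable: `inside` applies attention to
the convolutional branch before the shortcut addition (then rectifies the
sum); `outside` applies it to the rectified sum; `none` removes it, and
`residual = FALSE` removes the shortcuts, giving the full 2x2 ablation
grid with identical layer counts.

### Implementation

No deep-learning framework is involved: forward and backward passes are
implemented in the package, with convolution as im2col plus one BLAS GEMM
(compiled kernels unroll the receptive fields), and analytic gradients for
every layer including both attention variants. The test suite checks the
complete backward pass against central finite differences. Weights use
variance-scaling initialisation under a fixed seed; batch normalization
follows the standard per-batch moments with running statistics for
inference.

One consequence of small desk-scale runs deserves note: with only a few
dozen mini-batches, momentum-smoothed running statistics remain biased
toward their initial values, which can make inference-mode behaviour
diverge badly from training-mode behaviour. After the last epoch the
trainer therefore performs one additional forward sweep over the training
set and replaces the running statistics with exact population moments
(weights frozen). This is deterministic and removes the mismatch.

## Training and evaluation

The full-scale recipe is Adam at learning rate 0.01, batch size 32, 300
epochs, with categorical cross-entropy on the softmax outputs (the natural
choice for a softmax head). Inputs are normalised to [0, 1] by division by
the training-set maximum; raw 16-bit counts, and the wider composites,
cannot enter the network unscaled. The normalisation constant is stored in
the model and re-applied at prediction time.

Splitting is patient-grouped: patients, never images, are assigned to the
training or testing side, so augmented derivatives and repeat studies can
never leak across the boundary. Within each class the patient order is
randomised under the seed and patients assigned greedily until the class's
training images reach the target fraction — stratified, and exact whenever
each patient contributes one image. A patient holding more images than
either side's share triggers a warning and a best-effort split.

The evaluation suite computes the confusion matrix and one-vs-rest
accuracy, precision, recall, specificity and F1 per class. Headline numbers
are macro averages (unweighted over classes), matching the balanced-dataset
design; micro averages are reported alongside. Any metric with a zero
denominator is reported as 0 with a `degenerate` flag rather than raising
mid-evaluation. ROC analysis produces one one-vs-rest curve per class with
trapezoidal AUC — equal to the concordant-pair rank probability, which the
tests verify by exhaustive pair counting — a macro AUC as the headline
number, and a micro-averaged pooled curve for single-curve presentation.
`merge_metastatic = TRUE` collapses the two metastatic classes (summing
their probabilities) for the two-class metastatic-vs-not view.

## The phantom generator

The generator exists so the entire pipeline is testable: it emulates the
*format and statistics* that matter for the pipeline, not anatomy. A
procedural skeleton (head ellipse, spine column, rib bands, shoulder/arm
and leg strips, pelvis) defines an expected-count template with elevated
spine/pelvis uptake; the anterior view draws Poisson counts from it, and
the posterior view is the mirrored template with a mild per-study intensity
asymmetry (uniform on [0.9, 1.1]) and independent Poisson noise. Two
class-independent confounders — a urinary-bladder hotspot and an
injection-point hotspot, both with heavy-tailed (log-normal) amplitudes
well above lesion levels — reproduce the main sources of non-specific
signal.

Lesions are drawn per class from three configurable mixes: shape
(punctate, patchy, mottling — a small tight blob, a broad anisotropic blob,
and a cluster of small blobs), body region (chest-dominant by default:
55% chest, 20% pelvis, 10% skull, 15% limbs), and amplitude. The default
amplitude law is log-normal with median 72 counts and log-sd 0.6, chosen
so that about 44% of lesion amplitudes fall in [50, 100] counts — the one
quantitative intensity statement available for this lesion population —
with a realistic right tail. The `easy` preset separates the classes
structurally (many large hot patchy chest lesions for ADMet versus few
fainter punctate pelvis/limb lesions for nADMet) and exists for pipeline
sanity checks; the `hard` preset overlaps the mixes heavily, mimicking the
clinical difficulty of telling the two metastatic subclasses apart. What a
passing desk-scale test shows is therefore that the pipeline can learn
*separable* class structure end to end — not that clinical performance is
reproduced; real scans differ in anatomy, attenuation, scanner effects and
label noise.

## Numerical and scale choices

* Problem sizes: unit tests render phantoms at 256x64 or 128x32 (the
  geometry scales with height/1024); the end-to-end checks train on 20
  studies per class with inputs block-averaged 4x to 256x64, 20 epochs.
  These sizes were chosen as the smallest at which the easy cohort is
  reliably learnable.
* Desk-scale learning rate: 0.001. At the full-scale rate (0.01) training
  on tens of images oscillates without settling within 20 epochs; 0.001
  converges smoothly at this problem size. The full-scale default of the
  configuration object remains 0.01.
* Ties: hard labels take the first (lowest-index) maximal probability;
  spatial max-pooling and the channel max-pool route gradients to the first
  maximum.
* Degenerate inputs: an all-zero image has no critical points ("empty body
  region" error); a training split missing a class errors before any work;
  zero-denominator metrics are flagged, not thrown.
* Rotation by 0 degrees and translation by 0 pixels are exact identities;
  augmentation never emits an untransformed copy (when neither transform is
  drawn, a rotation is forced).

## Known limitations

* The phantom is a statistical stand-in, not an anatomical atlas; results
  on it bound nothing about clinical data.
* Alignment is translation-only by design; scans whose two views differ in
  scale would need registration beyond the critical-point scheme.
* Training is CPU-bound R/BLAS; full-scale (1024x256, 300 epochs, ~1900
  images) runs are possible in principle but meant for patient users —
  the package's own experiments run at desk scale.
* The two-class merge sums class probabilities; a natively two-class head
  (`num_classes = 2`) is also available but trained separately.
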