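---
title: "Manipulation-based data augmentation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Manipulation-based data augmentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pestaug)
```

## The method

Small curated pest-image collections — here a six-class castor insect-pest
collection of 372 photographs with per-class counts between 44 and 84 — are
too small to train deep classifiers without severe overfitting. The
framework implemented in this package expands such a collection with
*manipulation-based* (pixel- and coordinate-level) transforms, all of which
are label-preserving: the augmented image `x_a = f_m(x_i)` keeps the class
label `y_i` of its source.

The proposed pipeline is a cascade rather than a flat menu of transforms.
One pass over a source image:

1. draws **three random center rotations** of the source;
2. stores the first rotated copy as is;
3. **histogram-equalizes** the second copy (per RGB channel) and stores it;
4. adds **Gaussian noise** to the third copy and stores it;
5. **scales** the equalized copy and the noisy copy (central crop, resize
   back) and stores both.

Five images are stored per pass. With the default three passes and the
untouched original retained, every source image yields
`5 × 3 + 1 = 16` images, which is exactly the expansion printed for the
collection's first and last classes (54 → 864, 44 → 704). The cascade mimics
what field conditions do to hand-held photographs: arbitrary orientation,
illumination changes, sensor noise, and variable framing.

The per-class expanded counts published for the four middle classes are not
exact multiples of a common factor; the count law implemented here is exact
(`n × expansionFactor`), and no post-hoc duplicate filtering is applied.

## Atomic transforms and their contracts

Every operator preserves the label, the raster dimensions, and the 8-bit
integer range, computing in double precision and quantizing once with a
single rule: round half away from zero, clip to [0, 255]. One rule makes
all outputs bit-reproducible across platforms.

* **Rotation** applies the 2×2 rotation matrix about the raster center by
  inverse mapping. At multiples of 90° on square rasters it is an exact
  pixel permutation; elsewhere it resamples bilinearly (or nearest-neighbor
  on request). Out-of-canvas preimages are filled by symmetric reflection by
  default — constant fill would paint dark corner wedges that a classifier
  could exploit as a spurious rotation cue. The cascade draws its angles
  uniformly from [0°, 360°); the stand-alone rotation benchmark preset uses
  the narrower benchmark range [0°, 150°]. Both ranges are honored in their
  respective contexts because they are specified independently.
* **Flips** reverse columns (horizontal) or rows (vertical); exact
  involutions.
* **Gaussian noise** adds an independent draw per pixel and channel.
  The default σ = 10 on the 0–255 scale is a visually perceptible but
  class-preserving level; σ is a configuration knob.
* **Histogram equalization** remaps each channel independently through
  `out(v) = round((cdf(v) − cdf_min)/(N − cdf_min) × 255)`. The mapping is
  monotone; a constant channel is returned unchanged (the denominator
  degenerates to zero and identity is the only label-safe convention).
  Applying the operator twice moves no pixel by more than one level.
* **Scale-in** crops the central `⌊side/zoom⌋` window and resizes back
  bilinearly; default zoom 1.25, a modest central zoom that keeps the
  subject in frame. The "scale in/out" benchmark additionally uses the
  reflective-pad zoom-out complement.
* **Mixup** forms `λ·X_i + (1−λ)·X_j` with λ = 0.2 between two *different*
  images of the *same* class; the partner is chosen uniformly at random
  among the other images of the class. Same-class pairing is what makes the
  operator label-preserving, so cross-class pairs are rejected outright.
* **Fancy-PCA** fits the 3×3 RGB covariance over all pixels of the dataset
  (each image resized to a 64 px working side for estimation only), keeps
  the smallest `k` components reaching 95% cumulative variance, and shifts
  every pixel of an image by `Σ_j p_j α_j λ_j` with `α_j ~ N(0, 0.1)`.
  The covariance is estimated on unit-scaled intensities so that the
  eigenvalue-weighted shift is a subtle color perturbation rather than a
  channel saturation; the shift is mapped back to the 0–255 scale before
  quantization. A zero-variance (constant) dataset is rejected as a
  degenerate covariance.

Randomized operators draw from substreams derived from a master seed and
the source-image id plus draw index, so results are independent of
iteration order and reproducible bit-for-bit.

## Benchmark strategies

Eleven presets (ids 0–10) mirror the published comparison design: baseline
(no augmentation), rotation, flips, contrast enhancement, noise, PCA,
mixup, scale in/out, rotation+scaling, rotation+flip+scaling, and the
proposed cascade. The comparison table does not state per-strategy dataset
sizes, so strategies 1–9 emit a fixed fan-out of two derived images per
source (flips and scale in/out produce exactly their two variants; contrast
enhancement is deterministic and contributes its single distinct copy) and
retain the originals, keeping the benchmark datasets comparable in size.
Whether the original images were retained in the published benchmark sets
is unstated; retention is the default here, consistent with the proposed
pipeline, and exposed as a flag.

`runComparison()` splits the original dataset 7:3 (stratified), augments
**only the training portion** with each strategy, trains the evaluation
classifier, and scores the held-out unmodified originals. Because
augmentation happens after the split, and every derived record inherits its
source image's id, no augmented derivative of a validation image can reach
training; the training routine additionally refuses any train/validation
pair that shares a source id.

## Evaluation harness

The classifier follows the transfer-learning protocol of the study: a
frozen convolutional feature extractor and a trainable two-layer dense head
— 512 rectified-linear units with dropout 0.5, then a softmax layer over
the classes — optimized with minibatch Adam (learning rate 0.001, batch 32)
on categorical cross-entropy, accuracy recorded every epoch. The published
dropout range 0.3–0.5 is realized as 0.5 on the hidden layer (stated
explicitly) and 0.3 at the backbone–head junction, the conventional
placement for the lower value.

The bundled `tiny` backbone is a seeded, fixed two-block random-convolution
stack (3×3 filters, ReLU, 2×2 mean pooling; 8 then 16 filters) over a
32 px input. Random frozen convolutional features are a standard
lightweight stand-in for pretrained features when only the head trains, and
they keep the full benchmark loop on one CPU in minutes. The `vgg16`,
`vgg19` and `resnet50` presets wire in the published input sides (224, 224
and 124 px — the latter kept as printed even though 224 is canonical for
ResNet50) but require pretrained convolutional weights that cannot be
bundled, so building them raises a capability error. Which backbone layers
were trainable in the published runs is not derivable from the printed
parameter counts, so the head-only default is used.

Accuracy is the fraction of correct predictions. The contribution of an
augmentation strategy is `100 × (acc_aug − acc_base)/acc_base`, *truncated*
to two decimals: truncation, not half-up rounding, is the rule that
reproduces both published contribution figures from their underlying
accuracy pairs (15.54 from 15.5498…, 5.73 from 5.7352…).

## Synthetic fixtures

The fixture generator emulates the *structure* of the curated collection —
six classes, imbalanced counts 54/84/49/69/72/44, variable content — not
pest morphology. Each class archetype fixes a body color, ellipse
elongation, body size, spot-texture density and background palette; each
image jitters position (±20% of the frame), orientation (uniform), scale
(±20%) and hue (±8%) under its own derived seed. The defaults (128 px
images, the archetype parameters) were chosen once as a realistic level of
within-class variation for hand-held pest photographs and are not tuned.

The archetypes are pairwise distinguishable and carry learnable signal (a
color-centroid classifier beats chance by a wide margin), so
augmentation-versus-baseline comparisons on fixtures are meaningful. What
fixtures cannot show: photographic clutter, occlusion, pose articulation,
or inter-class similarity of real pest photographs. A passing directional
result on fixtures demonstrates that the pipeline helps a classifier
generalize over the nuisance factors the generator models; it does not
certify the published absolute accuracies, which would require the original
photographs and GPU-scale training.

## Numerical choices and degenerate inputs

* One quantization rule everywhere (round half away from zero, clip).
* Bilinear resampling maps destination pixel centers by
  `src = (dst − 0.5)·(S/D) + 0.5`, which is the exact identity when sizes
  match; edge handling clamps for resize and reflects for rotation fill.
* Split sizes use round-half-up on `0.7·n` per class, with both sides of
  every class kept non-empty; stratification error is at most one record
  per class.
* Constant channels equalize to themselves; constant datasets are rejected
  by the PCA fit; mixup rejects self-pairs; zoom below 1 and negative σ are
  validation errors.
* Head training standardizes backbone features to train-set mean and
  standard deviation (floored at 1e-6) before optimization.

## Problem sizes used in the shipped experiments

The test suite runs its transform properties on small rasters (2–32 px)
where hand oracles are checkable, and its end-to-end directional experiment
on the full 372-image fixture set at 128 px with the tiny backbone,
20 epochs, batch 32, Adam 0.001, five seeded repeats of
cascade-augmented versus baseline training. These sizes keep the entire
suite within a coffee break on one CPU while exercising every code path at
the fixture set's full scale.

## Known limitations

* The tiny backbone's random features are weaker than pretrained VGG
  features; absolute accuracies on fixtures are not comparable to published
  values (by design, only directions and counts are).
* Rotation at non-right angles on non-square rasters falls back to
  resampling even at 90°/270°, since the permutation would not fit the
  canvas.
* The duplicate-filtering step implied by the published middle-class counts
  is not modeled; the count law is exact.
* JPEG input requires the optional EBImage reader; the canonical on-disk
  format is PNG, chosen so augmented pixels round-trip bit-exactly.
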