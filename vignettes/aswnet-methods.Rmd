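---
title: "Methods: attention-gated W-shaped networks for nucleus instance segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attention-gated W-shaped networks for nucleus instance segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(aswnet)
```

## The problem

Quantitative cell biology on fluorescence microscopy starts with nucleus
segmentation: every pixel of a single DNA-channel image must be assigned
both a foreground decision and an object identity, so that touching or
clumped nuclei receive distinct labels. Plain semantic segmentation
(foreground vs background) merges touching nuclei; classical thresholding
and watershed pipelines need per-dataset parameter tuning and degrade on
noisy images.

`aswnet` follows the three-class reformulation: each pixel is classified
as *background*, *nucleus interior*, or *nucleus boundary*. The boundary
class is what makes instances separable — two touching nuclei are split
by their shared boundary ridge. A convolutional encoder–decoder predicts
the per-pixel class probabilities, and a seeded-growth post-processing
step converts the probability field into an instance label map.

## Pre-processing

**Grayscale normalisation.** Fluorescence images carry arbitrary offsets,
exposure differences and hot pixels. `normalize_grayscale()` linearly maps
the 0.1th and 99.9th intensity percentiles to 0 and 1 and clips; the
percentile (rather than min–max) form is deliberate, as a single saturated
pixel would otherwise compress the whole dynamic range. A constant image
maps to all zeros. Both percentiles are configuration.

**Three-class targets.** `instance_to_three_class()` renders an instance
mask into per-pixel classes. The boundary class is drawn on the *inner*
rim of each instance: instance pixels within `boundary_width` (default 2,
chessboard distance) of the instance's complement. The source annotations
only delimit instances, so whether the boundary class sits inside,
outside, or straddles the contour is an interpretation; the inner-rim
choice keeps the union of interior and boundary exactly equal to the
binarised instance mask, which the test suite asserts as an invariant. A
width of 2 px gives the boundary class enough pixels to be learnable (a
deliberately thick training-time boundary; the post-processing thins it
again). Instances so small that erosion would empty them keep their
innermost pixel (maximum distance to the complement, ties broken by
smallest row then column) as interior, so every annotated nucleus remains
seedable.

**Class weights.** The three classes are heavily imbalanced (background
dominates, boundary is rare). `compute_class_weights()` uses mean-
normalised inverse frequencies, `w_c = total / (3 * n_c)`, so balanced
data gives unit weights.

**Augmentation.** Rotations are restricted to multiples of 90 degrees and
axis flips, sampled uniformly over the resulting 16-element group. This
avoids interpolating categorical labels; arbitrary-angle rotation would
require label-aware resampling for little benefit on roughly isotropic
nuclei.

## The networks

`build_asw_net()` constructs the cascade ("W"-shaped) attention network:
three down-sampling and three up-sampling stages ordered
down–down–up–down–up–up, so the feature resolution traces a W. With
`f = base_filters` and geometric channel doubling per scale:

```
C0 = block(x; 1 -> f)                  full resolution
C1 = block(pool C0; f -> 2f)           1/2
C2 = block(pool C1; 2f -> 4f)          1/4
U1 = upconv(C2; 4f -> 2f)              1/2    attention gate 1 on C1
C3 = block([U1, gate1(C1)]; 4f -> 2f)
C4 = block(pool C3; 2f -> 4f)          1/4
U2 = upconv(C4; 4f -> 2f)              1/2    attention gate 2 on C3
C5 = block([U2, gate2(C3)]; 4f -> 2f)
U3 = upconv(C5; 2f -> f)               full   attention gate 3 on C0
C6 = block([U3, gate3(C0)]; 2f -> f)
logits = conv1x1([C6, x]; f+1 -> 3);  probabilities = softmax
```

Design points, all centralised in the builder so alternatives are
one-line swaps:

* **Conv block** = two 3×3 convolutions, each followed by per-channel
  normalisation (when enabled) and ReLU. Kernel size is configuration.
* **Down/up-sampling** = 2×2 max pooling and 2×2-stride-2 transposed
  convolution.
* **Skips merge by concatenation**, the convention this family of
  cascaded encoder–decoders is built on.
* **The raw input joins only the final block** (before the 1×1
  classification head), deliberately not the first up-sampling path: the
  first decoder stage should work from encoded features, not from the
  noisy raw image.
* **The middle skip re-enters C3**, the most recent features produced at
  the 1/2 scale. The exact source of this between-net connection is a
  wiring choice; C1 would be the alternative.
* **Attention gates** are additive: both the skip features and the
  gating signal (the upsampled decoder features, already at skip
  resolution) are projected by 1×1 convolutions to an intermediate width
  (half the skip channels), summed, passed through ReLU, projected to a
  single channel and squashed by a sigmoid; the resulting coefficient
  map in (0, 1) multiplies the skip features. The gates add parameters —
  `parameter_count(ASW) > parameter_count(SW)` is asserted in the tests —
  and their coefficient maps are exposed for visualisation
  (`cmd_visualize(..., what = "attention")`).
* **Normalisation statistics** are computed per image over the spatial
  plane, at training and at inference alike. With single-image batches
  this *is* the batch statistic; reusing it at inference keeps
  prediction deterministic, batch-size independent, and translation
  covariant (which the wrap-padding shift test exploits).

`build_sw_net()` is the identical graph with every gate replaced by the
plain skip; `build_u_net()` is a standard symmetric 3-scale U-Net
baseline with an 8f bottleneck.

The forward and backward passes run on a small reverse-mode tape over
dense arrays; convolutions are evaluated as im2col + BLAS matrix
products with the gather/scatter index maps computed in compiled code.
Gradients are exact and are verified against central finite differences
in the test suite. He-style initialisation is used throughout,
deterministic in `rng_seed`.

## Training

The loss is weighted cross-entropy over the three classes,

$$
L = \frac{-\sum_p w_{c(p)} \log \hat p_{c(p)}(p)}{\sum_p w_{c(p)}},
$$

with probabilities clipped at $10^{-7}$ before the log. Normalising by
the summed weights rather than the pixel count keeps the loss scale
comparable across imbalance settings, and unit weights reduce exactly to
plain cross-entropy (asserted in tests; the uniform-prediction value is
$\ln 3$).

Optimisation is RMSProp (decay 0.9), whose per-parameter adaptive
scaling provides the dynamic learning-rate behaviour; no external
scheduler is layered on top. Training stops early when the validation
loss fails to improve for `patience_epochs` (default 10) consecutive
epochs; "improve" means a strict decrease by more than $10^{-6}$, since
a plateau definition needs some delta against float noise. The weights
of the best validation epoch are restored on return (save-best).

Batch size, learning rate and epoch budget are exposed configuration
with defaults (1, $10^{-3}$, 50), not claims about any reference run.

## Interior expansion

The network's predicted boundary band is thick; the decoder both thins
it and separates instances. Pixels with interior probability strictly
above 0.5 are seeds; connected components (8-connectivity by default —
4-connectivity would fragment diagonally-touching seed regions) become
one nucleus each. Growth is then *synchronized*: at each iteration every
label's frontier may claim unassigned neighbour pixels, subject to:

* background must not be the dominant class at the candidate;
* the boundary probability along the step must be non-decreasing within
  a tolerance of $10^{-6}$ (ridge ascent), unless the candidate is
  interior-dominant;
* a pixel claimable by two different labels in the same iteration is
  *contested* and stays unassigned forever, which is what leaves the
  one-pixel separation between clumped nuclei;
* a frontier pixel whose onward step would *descend* the boundary
  probability (past the ridge crest) stops growing in that direction and
  is itself discarded at the end, unless it is an original seed pixel —
  the "last iteration" boundary pixels are removed so the final contour
  sits just inside the crest.

Synchronized (rather than sequential per-seed) iteration makes the
result independent of seed enumeration order; the contested rule then
resolves symmetric encounters without arbitration. Termination is capped
at the image diagonal. No minimum seed size is imposed; a single-pixel
seed is a legitimate (degenerate) nucleus hypothesis.

Marker-based watershed (`watershed_postprocess()`: Meyer flooding of
`p_boundary - p_interior` from the interior seeds, restricted to
non-background-dominant pixels) and plain threshold labeling
(`threshold_labeling()`: connected components of argmax-interior) are
provided as the ablation alternatives. On ideal probability maps built
from ground truth, interior expansion dominates threshold labeling in
AJI because thresholding forfeits the whole boundary band; the test
suite asserts this ordering.

## Metrics

All metrics are computed on the 0–1 scale (percent is a reporting
option):

* **DICE1** — pixel Dice over binarised foregrounds; both-empty is 1.
* **DICE2** — object-level ensemble Dice; published variants differ, so
  the implemented form is fixed here: match each truth object to its
  maximal-overlap prediction and vice versa, accumulate `2|p∩g|` and
  `|p|+|g|` over both directions, return the ratio of sums; objects with
  no overlap contribute their size to the denominator only.
* **AJI** — aggregated Jaccard: each truth object consumes the unused
  prediction with maximal IoU (ties broken deterministically by the
  smaller prediction label), intersections and unions accumulate, and
  every unused prediction inflates the union. The label tie-break makes
  the statistic deterministic; on irregular real or simulated masks,
  exact IoU ties do not occur and relabeling leaves the value unchanged.
* **PQ = DQ × SQ** — matches are IoU > 0.5 (necessarily one-to-one);
  `DQ = TP/(TP + FP/2 + FN/2)`; SQ is the mean matched IoU (0 if no
  matches).
* **Area correlation** — nuclei are matched one-to-one greedily by
  descending IoU and the Pearson correlation of matched areas is
  reported, the downstream consistency check for morphology analyses.

Datasets are scored per image and averaged unweighted; pooling pixels
across a test set would weight large-foreground images more, and
per-image averaging is the common benchmark convention.

Every metric is verified against independent brute-force oracles (direct
pixel counting with exhaustive pairing) on a thousand random mask pairs,
and against hand-derived toy values: a 2×2 square against its one-pixel
shift gives DICE1 = 0.5, AJI = 1/3 and PQ = 0 exactly.

## The synthetic data generator

`generate_nuclei_image()` emulates the two regimes the framework
targets: a clean, moderately dense single-DNA-channel screen and a
low-SNR acquisition. Nuclei are randomly oriented ellipses (axis ratio
1–1.8) whose boundary is perturbed by a low-order Fourier wobble
(harmonics 2–4, amplitudes ~N(0, 0.03)), filled with a quadratic radial
intensity falloff and per-nucleus brightness variation of ±20%. A
configurable fraction of nuclei is placed touching an existing neighbour
— adjacent pixels, distinct labels, never shared pixels — to exercise
clump separation. Noise is additive Gaussian, scaled so the mean
in-nucleus signal over the noise standard deviation matches the target
SNR (the realised SNR is asserted within 20% in tests), with optional
Poisson shot noise; the negative noise tail is shifted, not clipped, so
the noise statistics survive conversion to integer counts. Density
presets (low/medium/high) map to target foreground coverage of 5%, 12%
and 25%.

What the simulator does *not* model: illumination gradients, textured
chromatin, mitotic figures, out-of-focus blur, or annotation error.
Passing tests on synthetic data therefore demonstrate that the
architecture, optimiser, decoder and metrics are correctly implemented
and that the pipeline can learn and recover instances under controlled
conditions — not that any particular accuracy transfers to a specific
real dataset. The split layout mirrors the 100/50/50 partition
convention of the public benchmark the defaults emulate.

## Reference problem sizes

The package's own reference experiment — also what
`scripts/acceptance.R` reruns — uses 40 training, 10 validation and 10
test images of 128×128 pixels with ~8 nuclei each, a base_filters = 4
ASW-Net, learning rate 2×10⁻³, at most 30 epochs. These sizes were
chosen so the whole cycle is a single-CPU, minutes-scale computation
while still containing clumped nuclei and a meaningful train/val/test
structure. Unit tests use smaller instances of the same generator.

## Numerical and degenerate-input choices

* Probabilities are clipped at $10^{-7}$ before logs; probability maps
  must sum to 1 within $10^{-5}$ per pixel.
* Max-pooling ties take the first element in fixed (row, column) order;
  AJI ties take the smaller prediction label; innermost-pixel ties take
  the smallest row, then column.
* Constant images normalise to all zeros rather than dividing by zero.
* Inputs not divisible by 8 are reflect-padded to the next multiple for
  the forward pass and the logits cropped back, so 520×696-style frame
  sizes work unchanged.
* Empty-vs-empty mask comparisons define all metrics as 1; an empty
  prediction against non-empty truth scores 0.
* Label maps with labels above 65535 are stored as a two-page 16-bit
  TIFF (high and low words), lossless to 2³²−1; 32-bit TIFF float
  storage is quantised at 2⁻³², which bounds probability-map round-trip
  error at ~10⁻⁹.

## Known limitations

* CPU-only, single-image batches; the implementation favours exactness
  and auditability over throughput, and large-scale training (hundreds
  of full-resolution images) is outside its intended envelope.
* The three-class boundary rendering assumes instances are disjoint
  label sets; overlapping-nucleus annotations (rare in 2-D fluorescence)
  are not representable.
* Attention coefficients are diagnostic, not causal explanations.
* The simulator's nuclei are star-convex by construction; strongly
  lobed or ring-shaped objects are not generated.
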