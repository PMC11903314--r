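---
title: "Promptable interactive and automatic instance segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promptable interactive and automatic instance segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promptSeg)
```

# The problem

Identifying individual objects — cells, nuclei, organelles — in microscopy
images is a bottleneck of quantitative biology. Fully automatic segmenters
degrade on data unlike their training distribution, and correcting poor
automatic results by hand is slow. Promptable segmentation reframes the
task: the user (or a simulation of one) marks an object with a point, a box
or a rough mask, and a model returns that object's mask in milliseconds.
Because the expensive image encoder runs once per image and only a light
decoder reruns per prompt, interactive correction is cheap, and the same
backbone can drive fully automatic instance segmentation.

promptSeg implements this method stack in R, decoupled from any particular
network through a *promptable-model contract*:

* `embedImage(model, image)` — prompt-independent features, computed once;
* `predictMasks(model, embedding, prompts, multimask)` — mask logits plus a
  self-estimated IoU; exactly three candidate masks when a single,
  inherently ambiguous point prompt is given;
* `aisPredict(model, embedding)` — three dense channels (foreground,
  center distance, boundary distance) for automatic instance segmentation.

Two reference implementations ship with the package: a ground-truth-driven
**oracle** (a deterministic test double that anchors every protocol test)
and a small trainable **toy model** (below). Everything in the package —
prompt simulation, training, evaluation, calibration, volumetric
projection — talks to the contract only, so the algorithms would apply
unchanged to a large pretrained backbone.

# Coordinates and data representations

Images are numeric matrices (`H x W`) or arrays (`H x W x C`, `C <= 3`);
label images are non-negative integer matrices with 0 as background;
volumes and time series are `Z/T x H x W` arrays. Coordinates are 1-based
`(row, col)` with pixel-center semantics and boxes inclusive on both ends —
the R convention throughout, chosen so that `which(mask, arr.ind = TRUE)`
and box arithmetic compose without off-by-one adjustments. Encoders expect
three channels: one-channel images are replicated, two-channel images are
averaged and the mean replicated (losing information, but preserving the
input statistics of a three-channel backbone); intensities are min–max
normalized per image to [0, 1] before the model — a deterministic,
scale-free choice.

# Prompt simulation

Both training and evaluation simulate an annotator from ground truth:

* the *initial prompt* for an object is either one positive point, uniform
  over the object's pixels, or the object's tight bounding box;
* each *correction round* samples one positive point uniformly from the
  missed region (gt ∖ prediction) and one negative point uniformly from
  the spurious region (prediction ∖ gt); if a region is empty the sampler
  falls back to uniform inside (respectively outside) the object;
* prompts accumulate: all points sampled so far, the initial box if one
  was given, and optionally the previous prediction's logits as a
  low-resolution *mask prompt*.

Uniform sampling (with replacement across rounds) is the simplest unbiased
choice. All samplers take explicit seeds and never leak state into the
caller's random stream.

# The mean segmentation accuracy

Quality is measured per image by the segmentation accuracy at IoU
threshold $t$,
$$\mathrm{SA}(t) = \frac{\mathrm{TP}(t)}{\mathrm{TP}(t) + \mathrm{FP}(t) + \mathrm{FN}(t)},$$
after one-to-one instance matching that maximizes total IoU over pairs
with IoU *strictly greater* than $t$ (a tie at $t$ is unmatched), and the
mean segmentation accuracy (mSA) averages SA(t) over
$t \in \{0.50, 0.55, \dots, 0.95\}$. For $t \ge 0.5$ and disjoint
instances the matching is provably unique (two disjoint predictions cannot
each cover more than half of one object's union), so the implementation
sweeps thresholds over one pairwise IoU table; below 0.5 it solves the
assignment exactly with a Hungarian algorithm, and the test suite checks
both regimes against brute-force enumeration over all one-to-one
matchings. Conventions the literature leaves open: two empty images score
1.0, exactly one empty image scores 0.0; dataset scores are unweighted
means over images.

# Automatic instance segmentation (AIS)

The AIS head predicts three channels in [0, 1]: foreground probability,
distance to the object center and distance to the object boundary, each
distance normalized per object by its maximum. Background pixels carry
center distance 1 and boundary distance 0; a single-pixel object has
boundary distance 1 by convention; when the centroid of a non-convex
object falls outside it, the innermost pixel (maximal boundary distance)
serves as its center, so seeds always lie inside objects.

Decoding is a seeded watershed:

* seeds = connected components of
  (center < `centerThreshold`) ∧ (boundary > `boundaryThreshold`) —
  boundary-distance dips split the seeds of touching objects, center
  distances keep non-convex objects in one piece;
* mask = foreground > `foregroundThreshold`;
* heightmap = 1 − boundary distance (interiors are basins, interfaces
  ridges), implemented as a priority flood in which every pixel queues at
  its own height and ties resolve by insertion order — deterministic, and
  exact on ideal channels. A config switch offers the alternative
  composition 0.5·(center + 1 − boundary);
* instances below `minObjectSize` (default 10 px) are removed.

Defaults are 0.5 for all three thresholds. The binding design test is the
round trip: for synthetic labels with radii ≥ 4 px, including touching
pairs, `aisSegment(computeDistanceTargets(L))` reproduces `L` at mSA 1.0.
Fine-tuned predictors are better served by recalibrated thresholds, so
`gridSearchAIS()` sweeps them over cached channels on a validation set and
returns the argmax (first-in-grid on ties) with the full score table.

# Automatic mask generation (AMG)

AMG proposes masks from a regular point grid (`pointsPerSide`² points,
half-cell offset from the borders), predicting three candidates per point.
Candidates are dropped if their predicted IoU or *stability score* — the
IoU between the masks thresholded at logit ±δ (δ = 1 by default) — falls
below threshold, or if they are smaller than `minObjectSize`. Greedy
non-maximum suppression by descending predicted IoU keeps an antichain
under mask overlap (`nmsIou` = 0.7), and label rendering paints kept masks
in ascending score order so the best mask wins residual overlaps. Default
filter thresholds (0.88 predicted IoU, 0.95 stability) follow common
promptable-segmentation practice; models fine-tuned on microscopy are
better calibrated and need lower values, hence `gridSearchAMG()`
precomputes raw candidates once and sweeps both thresholds.

# The toy promptable model

No deep-learning framework is assumed: the toy model is a small
convolutional network written in vectorized base R (im2col convolutions,
hand-derived gradients, Adam). It mirrors the encoder / prompt-encoder /
mask-decoder decomposition of its large-scale counterparts:

* **encoder** — 3×3 conv (3→8) + ReLU, 4× average pooling, 3×3 conv
  (8→16) + ReLU: a 16-channel embedding at ¼ resolution;
* **prompt encoder** — prompts rasterized at embedding resolution into
  four channels (Gaussian splats of width `promptSigma` = 8 px around
  positive and negative points, box interior, squashed mask-prompt
  logits), then a 1×1 conv;
* **mask decoder** — 3×3 conv over the concatenated features, one
  single-mask and three multimask logit maps, bilinearly upsampled, plus
  sigmoid IoU estimates from pooled hidden features;
* **AIS decoder** — a parallel head emitting the three AIS channels;
* **full-resolution skips** — the first encoder layer's features enter
  both heads through 1×1 convolutions at full resolution. The coarse
  decoder output gates *which* object is meant; the skip restores
  boundary detail that ×4 upsampling cannot carry. Without it, masks are
  too blurry to score under the stringent upper mSA thresholds.

The model has ~9,000 parameters — deliberately small so that training runs
in minutes on one CPU core; it is a desk-scale stand-in, not a claim of
equivalence to transformer backbones (its rasterized prompt encoding, in
particular, replaces positional-encoding attention). Weights initialize
He-style from a fixed seed. Parameter groups (`encoder`, `prompt_encoder`,
`mask_decoder`, `ais_decoder`) can be frozen individually, supporting
partial fine-tuning studies.

# Training

`fitPromptable()` implements iterative interactive training interleaved
with AIS training. One interactive iteration per image: embed once, sample
up to `nObjectsPerImage` (default 8) objects, and for each object run
`nSubIterations` (default 8) prompt rounds — the initial point-or-box
prompt (fair coin; the multimask path with best-of-3 selection by
predicted IoU applies exactly when the prompt is a single point), then
correction rounds that sample a point pair from the current errors and
feed the previous mask back with probability 0.5 (from round 1 on; round 0
has no previous mask). Losses: soft Dice between mask probabilities and
the object, squared error between the predicted IoU and the measured IoU
of the thresholded mask. The soft Dice uses the squared-denominator form
$1 - 2\sum pt / (\sum p^2 + \sum t^2)$, which equals mask Dice on hard
inputs. All sub-iteration losses are averaged into one gradient step. The
interleaved AIS iteration reuses the same images, derives the three target
channels from the ground truth, and applies the mean of three Dice losses
with the two distance channels masked to the foreground.

Validation per epoch: box + one random positive point per object, scored
by hard-mask Dice, plus (1 − AIS loss); the two add up. The learning rate
halves after 3 epochs without improvement (plateau schedule), training
stops after 10, and the best-validation weights are restored. The default
learning rate is 2e-3: the plateau/early-stopping mechanics follow
fine-tuning practice, but a from-scratch ~9k-parameter network needs a far
larger rate than the 1e-5 used to nudge pretrained transformer weights.
Training is deterministic for a fixed config seed on a single thread.

# Interactive evaluation protocol

`simulateInteractiveSegmentation()` scores a model the way a user would
experience it: per object, an initial point or box prompt, then seven
correction rounds; after every round the per-object masks are assembled
into one label image (overlaps resolved by predicted-IoU order) and scored
by mSA, yielding an 8-entry curve. The mask prompt is either always fed
back or never, as two separate protocol variants. Per-object aggregation
is also available through the trace, but assembled-image mSA is the
default since it matches the reported metric. With the exact oracle the
curve is identically 1.0 for any seed and start mode; with a dilate(2)
oracle it is constant at the analytically enumerable threshold-count value
— the two anchors that pin the protocol's correctness.

# Volumes and time series

Volumetric segmentation and tracking reuse the 2D engine slice by slice:

* **interactive projection** — segment the seed slice, then march
  outward, prompting each adjacent slice with the previous mask's bounding
  box and the mask itself as a mask prompt (optionally its centroid as a
  positive point); a direction stops on an empty prediction or a
  slice-to-slice IoU below `stopIou` (default 0.5; structures whose
  cross-sections shrink to a few pixels, like sphere poles, need a
  permissive value);
* **automatic volumes** — per-slice AIS or AMG, then bipartite linking of
  consecutive slices (greedy one-to-one by descending IoU above
  `linkIou`), chains sharing one id, chains shorter than `minExtent`
  removed. Merging only relabels; per-slice partitions are preserved
  exactly;
* **tracking** — the same marching logic along time, forward from the
  seed frame (optionally backward). Divisions and merges are out of
  scope; anisotropy is ignored (no z-scaling of IoU), consistent with
  per-slice processing.

# The synthetic generator

`generateBlobs2D()`, `generateVolume()` and `generateTimeseries()` emulate
fluorescence microscopy of nuclei-like objects: bright ellipses
(ellipsoids) on a dark background, default intensities 0.8 vs 0.2 with
additive Gaussian noise σ = 0.05, radii 6–10 px, and a configurable
fraction of objects placed so that masks share a boundary without
overlapping — the touching case that distance-based decoding must split
and grid proposals tend to merge. Placement uses bounded rejection
sampling and raises an explicit infeasible-packing error. Volume centers
snap to integer voxels so a radius-r sphere spans exactly 2r+1 slices;
time-series drift uses integer steps so ground-truth tracks displace by at
most `driftPerFrame` per axis exactly. The generator is a pure function of
its spec (including the seed).

What passing tests on this generator do **not** show: robustness to real
microscopy's textured backgrounds, intensity gradients, out-of-focus
light, shot noise, or densely packed irregular morphologies. The generator
exists to verify the algorithmic machinery — metrics, decoding, training
dynamics, protocol bookkeeping — not to certify biological performance.

# Numerical choices and degenerate inputs

* Strict IoU inequality at matching; ties broken lexicographically.
* Empty masks: IoU and Dice of two empty masks are 1.0.
* Watershed ties resolve by queue insertion order (stable, deterministic).
* Distance transforms treat the image border as background, so objects
  touching the border get finite boundary distances.
* Single-pixel objects: center distance 0, boundary distance 1.
* Constant images normalize to all zeros.
* Images are zero-padded (bottom/right) to the encoder's stride multiple
  and to the training patch; predictions are cropped back.
* Checkpoints store architecture plus raw weight matrices; reloading
  reproduces predictions bit-exactly.
* TIFF convention: ≤16-bit samples are integer data (exact round trip up
  to 65535), 32-bit samples are unit-interval intensities (2⁻³²
  precision). Label files must be integer-typed; float files are rejected.

# Problem sizes used by the shipped tests

The test suite and the acceptance script regenerate everything from code:
64×64 images with 4–6 objects for unit and protocol tests, 50 images for
the AIS round trip, 200 random label pairs for the brute-force matcher
comparison, a 16-image training set (5 blobs each) fitted for at most 40
epochs for the parameter-recovery study, and 21×48×48 volumes for the
volumetric round trips. These sizes were chosen so the whole suite runs on
a single CPU core in a few minutes while leaving each property's failure
modes observable.

# Known limitations

* The toy model's receptive field (~25 px) caps the object sizes it can
  segment from a single point; the oracle, not the toy model, anchors
  protocol correctness.
* Mask prompts are consumed at embedding resolution; providers must
  downsample.
* AMG is single-scale (no multi-crop proposal pyramid).
* Tracking handles one object per track and no divisions.
* No tiled processing: images must fit in memory at native resolution.
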