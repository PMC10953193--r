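---
title: "Methods: a 3D region proposal network for pulmonary nodule detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a 3D region proposal network for pulmonary nodule detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The detection problem

Low-dose chest CT screening produces hundreds of slices per patient, and the
finding that matters most — the pulmonary nodule — is a roughly spherical,
often faint object between a few millimetres and a few centimetres across.
`lungrpn` implements a one-stage 3D region proposal network (RPN) for this
task: a convolutional backbone extracts features from a 3D patch, an optional
feature-pyramid neck fuses them across resolutions, and a dense head predicts,
at every anchor position, a probability and a cubic box `(z, y, x, d)`.
Because nodules are nearly spherical, anchors are cubes of 5, 10 and 20
voxels, all three attached to every cell of each pyramid level (levels at
strides 2, 4 and 8 relative to the input patch), so each head emits
`3 anchors x 5 outputs = 15` channels.

The package covers the full pipeline — preprocessing, synthetic phantom
generation, the model and its training-sample assignment rules, sliding-window
inference with lung masking, and FROC/CPM evaluation — at a scale a single
CPU handles in minutes, so every component is testable end to end without
external imaging data or a GPU.

## Preprocessing

CT volumes are resampled to a 1 mm isotropic grid with trilinear
interpolation, and radiodensity is windowed from −1200 to 600 HU onto
`[0, 1]`, stored at single precision. The window spans air (≈ −1000 HU)
through soft tissue (≈ +40 HU) with headroom on both sides, so lung
parenchyma, ground-glass opacity and solid tissue all stay inside the linear
range. Two numerical choices are deliberately pinned down because they affect
exact test values:

* output grid sizes are `round(size × spacing / target)` with *half away
  from zero* rounding (base R's `round` is half-to-even, which is
  platform-stable but surprising in tests);
* voxel indices are 0-based and refer to voxel centres, so resampling
  preserves the world position of the volume centre to within one voxel.

Interpolation for intensities is trilinear; masks use nearest/threshold
logic. Axis order is `(z, y, x)` internally while annotation files use world
`(x, y, z)` millimetres, the dialect of the public LUNA16 tooling.

## The synthetic phantom cohort

Real cohorts for this task are either large external downloads or private.
The phantom generator emulates the statistical structure detection code
actually depends on:

* a body ellipsoid at soft-tissue density (+40 HU) containing two air-like
  lung ellipsoids (−850 HU), with additive Gaussian noise (20 HU);
* spherical nodules whose diameters follow a log-normal (median 8 mm,
  log-sd 0.45, truncated to 4–40 mm) — screening cohorts are strongly
  right-skewed, with most nodules under 10 mm;
* a *solid-component fraction* per nodule, drawn from a three-band mixture
  (0–10%, 10–50%, 50–100%, weights 0.3/0.4/0.3): each nodule is a
  ground-glass sphere (−600 HU) with a centred solid core (+40 HU) whose
  volume is the sampled fraction of the nodule volume (core radius
  `r·f^(1/3)`). This is a one-parameter geometric stand-in for the
  consolidation-to-tumour notion used when stratifying nodules from pure
  ground-glass to solid.

Nodules are placed entirely inside a lung with pairwise non-overlap, and
every phantom carries its exact lung mask and LUNA16-dialect annotations.
What the phantom does *not* model: airways and vessels, spiculated or
juxtapleural morphology, scanner/kernel noise. Passing tests on phantoms
therefore demonstrate that the detection machinery (assignment, training,
decoding, scoring) is correct and learnable — not that the trained weights
transfer to clinical CT.

## The model

Three backbone variants share one stage interface:

* **resnet** — plain residual blocks (two 3×3×3 convolutions);
* **resnext** — bottleneck residual blocks whose middle 3×3×3 convolution is
  grouped (cardinality `g`), the aggregated-transform design;
* **csp_resnext** — the ResNeXt block wrapped in a cross-stage-partial
  split: half the channels pass through the residual unit, half bypass it,
  and a 1×1×1 transition fuses the concatenation. This removes roughly a
  third of the block's parameters at equal width, which the tests assert.

The stem convolution carries the first stride-2 downsampling, so no feature
map is ever at full patch resolution; stages 2 and 3 downsample again,
giving levels at strides 2, 4 and 8 with widths 2×, 4× and 8× `base_channels`.
This placement of the first stride is a package design choice (stride
schedules for the reference architecture are not published) made for CPU
cost: it does not change the head contract. With the FPN enabled, 1×1×1
lateral projections are fused top-down (nearest-neighbour ×2 upsampling,
addition, 3×3×3 smoothing); without it, the lateral features go straight to
the per-level heads. Desk-scale defaults are `base_channels = 8`,
`cardinality = 8` (reduced automatically to divide the bottleneck width),
one block per stage, neck width 8. Normalisation is instance norm: batch
sizes here are tiny, so batch statistics would be meaningless.

The whole network — forward pass and reverse-mode gradients — is implemented
in the package (R orchestration over RcppArmadillo im2col/BLAS convolution
kernels). Gradient correctness is enforced by finite-difference tests at
every build.

## Training-sample assignment

Dense detectors must label each anchor positive, negative or ignored before
a loss can be computed.

* **IoU matching** (`assign_iou`): positive above 0.5 best-IoU, negative
  below 0.3, ignored between; unmatched ground truths are given their
  best-IoU anchor. Thresholds follow the RetinaNet lineage. This rule
  routinely yields several positives per nodule.
* **Nearest anchor** (`assign_nearest`): each ground truth gets exactly one
  positive — the anchor whose point is nearest its centre (ties: lexicographic
  `(z, y, x)`), and among sizes at that point the one nearest its diameter
  (ties: the smaller size). The motivation is that multi-positive IoU
  matching supervises several boxes of varying quality for one nearly
  spherical object, while a single well-chosen anchor suffices.

Two details are package decisions where the source material is silent: the
*ignore* rule under nearest-anchor (non-positive anchors with IoU > 0.3
against any ground truth are ignored rather than treated as negatives, so
near-hits are not penalised), and conflict resolution when two ground truths
select the same anchor (the closer one keeps it; the other takes its
next-best anchor — both the implementation and the test oracle encode this
rule independently). Anchor points sit at cell centres
(`grid index × stride + stride/2`).

Regression targets are `(gt_center − anchor_point)/anchor_size` per axis and
`log(diameter/anchor_size)`; decoding inverts the encoding exactly.

## Loss and optimiser

Classification is a sigmoid focal loss (α = 0.25, γ = 2) over positive and
negative anchors only, normalised by the positive count; regression is
smooth-L1 over positives with weight λ = 1. The loss form follows the
RetinaNet family, since the detector descends from it. The optimiser is
Ranger — RAdam wrapped in Lookahead (k = 6, α = 0.5) — with gradient
centralization (the per-filter mean is subtracted from convolution weight
gradients before the update); a plain Adam switch exists as a fallback. The
reference recipe is a constant learning rate of 0.001 over 200 epochs, and
those remain the `train_config()` defaults. Desk-scale runs are a different
optimisation regime — a ~100k-parameter network, batch size 1, and a few
hundred optimiser steps in total — so the desk preset raises the constant
rate to 0.0125 (batch 1), chosen by a one-patch memorisation diagnostic: at
0.001 the positive anchors barely move within a 30-epoch budget because the
~10^5 negative anchors of a 64-cubed patch dominate the early gradient,
while around 0.01 the loss converges and the ranking separates (0.02 and
above destabilises). For the same reason the head's probability-logit bias
is initialised to −6 (foreground prior ≈ 0.25%), which makes the initial
negative focal pressure negligible so no optimiser steps are spent on a
global suppression phase. No schedule is used in either regime.

Augmentation (random xy-plane flips, z-axis rotation uniform in 0–180°,
isotropic scaling 0.75–1.25×) applies one affine to both voxels (trilinear)
and annotation centres (exactly); diameters multiply by the scale factor
only, since rotations and flips leave a sphere's diameter unchanged.
Annotations pushed out of the patch are dropped with a message.

## Inference and post-processing

Whole volumes are tiled by a sliding window (default 64³ with 24-voxel
overlap — at least the largest anchor, so no nodule can straddle tiles
undetected), every anchor above a probability floor is decoded, and
cross-tile duplicates are merged by one global greedy 3D NMS at cube-IoU
0.1 (nodules are sparse, so a low threshold is right for duplicate merging).
The floor default is 0.05; weakly trained desk-scale models are
under-calibrated, so pipelines that rank detections (FROC) may reasonably
lower it and rely on the per-scan cap (default 100) instead.

Extrapulmonary false positives are removed by lung masking: keep a detection
iff its rounded centre voxel lies in the mask dilated by a 2-voxel margin.
When no precomputed mask exists, `compute_lung_mask()` thresholds below
−320 HU, discards border-connected air, keeps the two largest interior
components and fills enclosed holes (a solid nodule core would otherwise
punch a hole in its lung).

## Evaluation

Scoring follows the free-response protocol used by the LUNA16 challenge
family: a detection hits a nodule when its centre lies within the nodule
radius of the annotated centre; each nodule is credited once, to its
highest-probability hit; extra hits on a credited nodule are ignored (a
configuration flag counts them as false positives instead, for sensitivity
analyses). Sweeping the confidence threshold yields the FROC curve;
sensitivities are read off at 0.125, 0.25, 0.5, 1, 2, 4 and 8 false
positives per scan by linear interpolation (below the smallest achieved
rate the curve is interpolated towards `(0, 0)`; beyond the largest it is
held at the rightmost value), and their arithmetic mean is the competition
performance metric (CPM). Cross-validated runs aggregate per-fold values as
mean ± sample SD, with folds split by scan so no scan leaks across folds.

The package's exact worked examples pin the CPM arithmetic to published
sensitivity rows (e.g. a row reading 77.0/84.3/89.4/92.5/94.6/96.0/96.6 %
averages to 90.1 %); one published row whose printed CPM disagrees with the
mean of its printed sensitivities by 0.6 points is deliberately not used as
a test vector.

## The pruning ladder

`cmd_prune_ladder()` re-runs the ablation that motivates the architecture:
ResNet → ResNeXt → CSP-ResNeXt backbones without a neck, CSP-ResNeXt with
the FPN, and finally FPN with IoU-matching versus nearest-anchor assignment
— six configurations, one CPM each, on a phantom cohort at desk scale. The
first four rows use IoU matching (the pre-modification default; the source
table leaves the assignment column blank there). Desk-scale CPMs on
phantoms are not comparable to published full-scale values and are not
asserted against them; what the harness guarantees is the six-row structure
and bit-reproducibility under a fixed seed.

## Problem sizes and budgets

The shipped test and acceptance settings are deliberate package choices:
24 training patches of 64³ (75% positive fraction) drawn from 6 phantoms —
spreading the same patch budget over more phantoms roughly doubles the
number of distinct nodules seen and measurably improves held-out
sensitivity — 30 epochs at batch 1 with flip-only augmentation, and
evaluation on 8 held-out phantoms of 80×96×96 voxels. Flips quadruple the
effective pose diversity at no interpolation cost (they are exact array
reversals); the full rotation/scaling augmentation, by contrast, turns
every epoch into a freshly resampled task and demonstrably under-converges
within a ~720-step budget, so it stays reserved for longer runs. On one CPU
a training step costs well under a second and a full end-to-end run about
ten minutes. The memorisation check (loss → near zero on one patch) and the
held-out sensitivity check (≥ 0.8 at 8 FP/scan) are the package's
learnability guarantees at this scale; the residual misses are concentrated
in small, nearly pure ground-glass nodules, mirroring the difficulty
ordering reported for solid-component strata at full scale.

## Known limitations

* Phantoms are geometric; no claim is made about clinical performance.
* The backbone's exact stage widths/depths at full scale are not published;
  the architecture reaches ~1.4 M parameters at `base_channels = 32` but
  exact parameter-count parity is out of scope.
* Single-volume (instance) normalisation means batch statistics are never
  pooled; large-batch GPU training would likely prefer batch norm.
* DICOM ingestion, slice-thickness harmonisation beyond isotropic
  resampling, and a second-stage false-positive-reduction classifier are out
  of scope.
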