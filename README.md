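# lungrpn

3D region proposal networks for pulmonary nodule detection in chest CT — a
complete, desk-scale R toolkit: volume I/O and preprocessing, synthetic lung
phantoms, ResNet / ResNeXt / CSP-ResNeXt 3D backbones with an optional
feature-pyramid neck, IoU-matching and nearest-anchor training-sample
assignment, focal-loss training with the Ranger optimiser, sliding-window
inference with lung masking, and FROC/CPM evaluation.

## Who this is for

Researchers working on computer-aided detection of lung nodules in low-dose
CT who want the *detection machinery* — anchor assignment rules, the
cross-stage-partial grouped-convolution backbone, the free-response scoring
protocol — as inspectable, tested R code that runs end to end on one CPU in
minutes. Every component is exercised on synthetic phantoms, so nothing
requires external imaging data, a GPU, or private cohorts.

## The model in brief

A one-stage 3D RPN in the RetinaNet lineage. An input patch `x ∈ [0,1]^{64³}`
(CT windowed from −1200..600 HU) passes through a three-stage backbone and a
feature pyramid; at every cell of the stride-2/4/8 level grids, three cubic
anchors (5, 10, 20 voxels) predict

```
(p, Δz, Δy, Δx, Δd)   with   center = point + Δ·size,  diameter = size·exp(Δd)
```

so each head emits 3 × 5 = 15 channels. Training-sample selection is either
fixed-IoU matching (positive ≥ 0.5, negative < 0.3) or the **nearest-anchor
rule**: per ground truth, exactly one positive — the anchor with the closest
point, size ties resolved toward the closest size. The loss is sigmoid focal
classification (α = 0.25, γ = 2) over positive + negative anchors plus
smooth-L1 regression over positives. Evaluation is free-response: a detection
hits a nodule if its centre lies within the nodule radius; sensitivity is
read at 0.125–8 FP/scan and averaged into the CPM.

## Worked example

```r
library(lungrpn)

# a reproducible phantom cohort: lungs, noise, spherical nodules with
# ground-glass rims and solid cores
cohort <- generate_cohort(phantom_config(), n_scans = 3, seed = 1)
cohort[[1]]$annotations
#>     seriesuid   coordX   coordY   coordZ diameter_mm solid_fraction
#> 1 phantom_001 69.33981 28.22740 37.37968    12.70999     0.63839355
#> 2 phantom_001 32.75423 43.79734 53.23275    17.07330     0.83170318
#> 3 phantom_001 21.52290 47.46033 32.64981    11.59501     0.04178299

# preprocess and sample training patches
pp <- preprocess_config()                    # −1200..600 HU → [0,1], 1 mm grid
nv <- normalize_hu(cohort[[1]]$volume, pp)
patches <- sample_training_patches(nv, cohort[[1]]$annotations, pp, seed = 1)

# build and train the modified detector
model <- build_model(model_config("csp_resnext", use_fpn = TRUE), seed = 1)
model
#> <rpn3d_model> csp_resnext + FPN, base 8, 90,353 parameters
model <- train(model, patches, train_config(epochs = 10, batch_size = 2))

# whole-volume detection and scoring
dets <- sliding_window_detect(nv, model, inference_config(probability_floor = 1e-4),
                              lung_mask = cohort[[1]]$lung_mask)
res <- evaluate_detections(dets, cohort[[1]]$annotations, n_scans = 1)
```

`evaluate_detections()` prints the seven per-rate sensitivities and their
mean; the CPM of a published sensitivity row is one call:

```r
cpm(c(77.0, 84.3, 89.4, 92.5, 94.6, 96.0, 96.6))
#> [1] 90.05714        # 90.1 to one decimal
```

A command-line front end over the same functions lives in `inst/cli/lungrpn`
(`simulate`, `train`, `detect`, `evaluate`, `prune-ladder`); the
`prune-ladder` command re-runs the six-configuration backbone/neck/assignment
ablation on a phantom cohort and emits one CPM per row.

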