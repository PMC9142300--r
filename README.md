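# sparsevoxnet

Voxel-wise segmentation of 3D cardiovascular MR volumes into background,
myocardium, and blood pool with **SparseVoxNet** — a U-Net-style 3D
convolutional network whose encoder is built from *sparse blocks* (chains of
pre-activation convolution units whose every intermediate output is
concatenated into the following transition layer), mixed dilated
convolutions (rates 2, 3, 5) for large receptive fields at constant
parameter cost, a non-local spatial self-attention block, and a deeply
supervised dual-path decoder. The package is aimed at researchers in
volumetric medical image segmentation who want a fully inspectable,
dependency-light reference implementation: every forward and backward pass
is implemented here (R with compiled Rcpp/Armadillo kernels), with no
external deep-learning framework.

## What is inside

* **Network** — `network_config()`, `build_sparsevoxnet()`,
  `architecture_report()`, ablation switches (`use_attention`,
  `use_dilation`), width scaling for desk-scale runs.
* **Core blocks** — `conv_spec()`/`conv_unit()` (BN → ReLU → conv →
  dropout), `sparse_block()`, non-local `attention_block()`,
  `count_parameters()`, `receptive_field()`.
* **Training** — `svn_train()`: SGD (momentum 0.9, weight decay 5e-4,
  batch 8 of random 64³ crops at full scale), N(0, 0.01²) initialization,
  cyclic polynomial learning-rate decay restarting every 5000 iterations,
  dual-head cross-entropy with auxiliary weight 0.5, 90°-rotation
  augmentation, checkpoints, `recalibrate_bn()`.
* **Inference** — `predict_volume()`: overlapping crop tiling with
  per-voxel soft voting over crops and both decoder heads.
* **Metrics** — `dice()`, `adb()` (average symmetric surface distance with
  18-neighborhood surfaces), `hausdorff()`, `evaluate_segmentation()`.
* **Data** — NIfTI I/O (`read_volume()`, `write_volume()`), z-score
  normalization, crop sampling, CSV manifests, and a seeded synthetic
  cardiac phantom generator (`generate_phantom()`, `generate_dataset()`)
  so the whole pipeline runs without external data.
* **CLI** — `svn_cli()` / `inst/cli/sparsevoxnet.R` with subcommands
  `make-phantom`, `train`, `predict`, `evaluate`, `inspect-arch`.

## The model in brief

A 64³ crop passes through two stride-2 stems (1→16→16 channels),
self-attention at 16³ where each position aggregates all others via
`y_i = softmax_j(θ(x_i)·φ(x_j)) g(x_j)` added residually, two 7-layer
sparse blocks with growth rate 12 (channels 16→100→184, dilations
1,1,1,1,2,3,5, receptive field 29³), pointwise transitions, and a
64-channel decoder of two kernel-4 stride-2 deconvolutions with a
three-layer 1×1×1 head. A deeply supervised skip branch maps the first
transition output (16³×100) pointwise to 64 channels, upsamples ×4
trilinearly, and owns a second head; training minimizes
`CE(main) + 0.5·CE(aux)` and inference averages both heads. See the
methods vignette (`vignettes/sparsevoxnet-methods.Rmd`) for the complete
recipe and design rationale.

## Worked example

```r
library(sparsevoxnet)

# architecture self-check: the reference parameter table
net <- build_sparsevoxnet(network_config())
architecture_report(net)[, c("name", "stride", "kernel", "parameters")]
#>               name stride kernel parameters
#>             Conv_1      2      3        448
#>             Conv_2      2      3       6928
#>  Spatial attention      1      1        816
#>     Sparse Block_1      1      3      28596
#>             Conv_3      1      1      10100
#>     Sparse Block_2      1      3      55812
#>             Conv_4      1      1      11840
#>           Deconv_1      2      4     262208
#>           Deconv_2      2      4     262208
#>    Skip connection      1      1       6464
#>          Main head      1      1       8515
#>           Aux head      1      1       8515

# desk-scale end-to-end run on a synthetic phantom (~30 min on one core)
ph <- generate_phantom(phantom_config(extent = 96, noise_std = 0.05, seed = 7))
net <- build_sparsevoxnet(network_config(width_multiplier = 0.25, crop_size = 32L))
fit <- svn_train(net, list(list(image = ph$image, label = ph$label)),
                 train_config(batch_size = 4L, max_iter = 2000L,
                              restart_every = 2000L, val_every = 100L,
                              early_stop_dice = 0.955, seed = 1L),
                 crop_size = 32L)
img <- normalize_volume(ph$image)
set.seed(123)
net2 <- recalibrate_bn(fit$net, sample_crops(img, ph$label, 32L, 16L))
res <- predict_volume(net2, img, crop_size = 32L, stride = 16L)
evaluate_segmentation(res$label, ph$label)
#>        class label      dice       adb hausdorff
#> 1 myocardium     1 0.6307333 0.9573473  3.000000
#> 2 blood_pool     2 0.9208985 0.9834593  2.236068
```

The parameter counts printed above are the verifiable per-stage counts of
the reference architecture (weights + biases, batch-norm scalars excluded).
In the phantom run, the final `evaluate_segmentation()` table reports
per-class Dice (overlap, 1 = perfect), ADB (mean symmetric surface
distance, voxels, 0 = perfect), and symmetric Hausdorff distance (worst-case
boundary error, voxels) of the voted whole-volume segmentation against the
generating labels. The pattern mirrors the published full-scale behavior:
the blood pool is segmented well (training-crop Dice 0.98, whole-volume
0.92, boundaries within ~1 voxel), while the thin myocardial shell is the
hard class — at this quarter-width desk scale its boundary sits about one
voxel off (ADB 0.96), which costs a thin structure most of its Dice. The
same pipeline runs from a shell:

```sh
Rscript inst/cli/sparsevoxnet.R inspect-arch
Rscript inst/cli/sparsevoxnet.R make-phantom --out data/ --n 10 --seed 1
Rscript inst/cli/sparsevoxnet.R train --manifest data/manifest.csv --out run/ \
    --width-multiplier 0.25 --crop-size 32 --batch-size 2 --iters 2000
Rscript inst/cli/sparsevoxnet.R predict --checkpoint run/final.rds \
    --image data/phantom_008_image.nii.gz --out pred.nii.gz
Rscript inst/cli/sparsevoxnet.R evaluate pred.nii.gz data/phantom_008_label.nii.gz
```

## Scope

Training at the published patient-data scale (the HVSMR 2016 cohort, 64³
crops, 8000+ iterations) is out of scope for a CPU package; the phantom
suite verifies the implementation end to end at desk scale. No DICOM
ingestion, bias-field correction, resampling, test-time augmentation, or
CRF post-processing.
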