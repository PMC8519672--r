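# liverseg

Liver segmentation for abdominal CT in R, built around a **2.5D VNet**
generator trained adversarially against a **Wasserstein critic**.

Each axial slice is presented to the network together with its upper and
lower neighbours (the 2.5D stack); the network predicts the centre slice.
The encoder-decoder uses *series* convolutions — an intra-slice 1×3×3
kernel followed by an inter-slice 3×1×1 kernel, each with batch
normalization and ReLU — five encoder stages at widths (32, 64, 128, 256,
256), strided-convolution downsampling, transposed-convolution upsampling,
and **chained residual pooling** (CRP) on every skip connection. Training
minimizes the composite objective

    L = α · L_Dice + (1 − α) · L_BD,          α = 0.1 by default,

where `L_Dice = 1 − 2|A∩B| / (|A|+|B|)` is the soft Dice loss and
`L_BD = mean(φ_G · s)` is the boundary loss: the ground-truth signed
Euclidean distance map `φ_G` (negative inside the region `G`, zero on its
boundary, positive outside) weighted by the predicted foreground
probability `s`. An optional adversarial term `−λ · mean(critic scores)`
couples in the WGAN critic, whose weights are clipped to `[−c, c]` after
every update. Evaluation uses accuracy `(TP+TN)/(TP+TN+FP+FN)` and the
Dice coefficient `2TP/(2TP+FP+FN)`.

The package reads LiTS-style NIfTI pairs (`volume-*.nii` /
`segmentation-*.nii`) and CHAOS-style DICOM series directories, and ships
a deterministic synthetic **phantom generator** (deformed ellipsoid
"livers" in noisy volumes) so every component is testable without any
external download. No deep-learning framework is required: the package
carries its own compact network core with explicit reverse-mode
differentiation over BLAS-backed convolutions.

## Worked example

Generate a small phantom dataset, train the adversarial loop briefly, and
evaluate predicted masks against the ground truth:

```r
library(liverseg)

spec <- phantom_spec(shape = c(8, 32, 32), radius_range = c(0.25, 0.35),
                     deform_amplitude = 1, seed = 7)
dir <- file.path(tempdir(), "phantoms")
manifest <- generate_phantom_dataset(2, spec, dir)
ds <- load_triplet_dataset(dir)    # 16 slice-triplets with centre masks

cfg <- train_config(
  n_critic = 1, batch_size = 4, max_steps = 60, seed = 11,
  lr_generator = 1e-3,
  loss = loss_config(alpha = 0.1, adv_weight = 0),
  model = arch_spec(stage_channels = c(4, 8, 16, 16, 16), dropout_rate = 0.1),
  critic = critic_spec(channels = c(8, 8, 8, 8), fc_width = 8,
                       input_hw = c(32, 32)))
fit <- train_adversarial(ds, cfg)
tail(fit$history$generator, 3)
#>  step        total dice_part boundary_part adv_part
#>    58 -0.005606962 0.1898583   -0.02732533        0
#>    59 -0.019003406 0.1583107   -0.03870497        0
#>    60 -0.027057422 0.1699491   -0.04894704        0
```

The `total` column recomposes exactly as
`0.1 * dice_part + 0.9 * boundary_part + λ * adv_part`; the boundary part
goes negative as probability mass settles inside the true region (its
minimum is attained by the ground truth itself).

```r
vol  <- read_nifti_volume(file.path(dir, "volume-0.nii"))
mask <- predict_volume(fit$generator, vol, window = window_spec())
pred_dir <- file.path(tempdir(), "pred")
# ... write masks with write_mask(), then:
evaluate_volumes(pred_dir, dir)
#>    case   TP FP  FN    TN accuracy   dice
#>       0  783 17 103  7289   0.9854 0.9288
#>       1  505 11 105  7571   0.9858 0.8970
#>  pooled 1288 28 208 14860   0.9856 0.9161
```

Per-volume rows report voxelwise confusion counts, accuracy and Dice; the
`pooled` row sums counts across volumes before dividing (so pooled Dice is
not the mean of per-volume Dice). After 60 training steps on 16 triplets
the network already reaches a pooled Dice of 0.92 on its training
phantoms — a plumbing demonstration, not a clinical benchmark.

## Command line

A thin CLI over the same functions lives at `inst/cli/liverseg.R`
(installed under `system.file("cli", "liverseg.R", package = "liverseg")`):

```sh
Rscript liverseg.R make-phantoms --n 4 --shape 16,64,64 --seed 42 --out data/
Rscript liverseg.R train    --config cfg.yaml --data data/ --out run/
Rscript liverseg.R predict  --model run/generator.rds --volume data/volume-0.nii --out pred/segmentation-0.nii
Rscript liverseg.R evaluate --pred pred/ --truth data/
```

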