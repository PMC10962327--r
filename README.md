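# qsmadapt

Field-to-susceptibility inversion for quantitative susceptibility mapping
(QSM) with an **adaptive-convolution 3D U-Net**: a deep dipole-inversion
network whose first-stage convolution weights are generated at run time by a
small *filter-manifold network* (FMN) from the acquisition side information
— the voxel size in mm and the B0 field direction in image axes — so that a
single trained model generalizes across image resolutions and tilted fields
of view.

## The problem and the model

Gradient-echo MRI measures the local field perturbation `B` induced by the
tissue susceptibility distribution `χ` (ppm).  In k-space,

    B̂(k) = d(k) · χ̂(k),        d(k) = 1/3 − (k·ô)² / |k|²,

where `ô` is the unit B0 direction.  `d` vanishes on the cone at the magic
angle `arccos(1/√3) ≈ 54.7°`, making the inversion ill-posed.  Voxel size
and field-of-view tilt change `d`, so a network that inverts the dipole
model must know the acquisition geometry.  Here that knowledge enters
through the side-information vector `s = (vx, vy, vz, ox, oy, oz)`: a
four-layer fully connected FMN (widths 6 → 12 → 48 → 196 → 13,824) maps `s`
to the weights of the 16 → 32 convolution of the first encoder block of a
standard 3D U-Net (16 initial channels, batch norm + ELU, 2³ transposed
convolution upsampling, global input→output residual skip; ≈ 8.3 M
trainable parameters in total).  Training pairs synthetic susceptibility
scenes with forward-simulated fields and minimizes the physics-consistent
loss `L = ‖χ_gt − χ_rec‖² + λ‖B_gt − χ_rec ⊛ d‖²` (λ = 1) with AdamW under
cosine annealing with warm restarts; transfer learning to measured data
freezes the adaptive layer and fine-tunes the decoder at a higher learning
rate.

The package is self-contained scientific R: the dipole physics, phantom
generator, FMN, U-Net (with hand-derived analytic gradients on
Rcpp/Armadillo kernels), training loops, and NRMSE/SSIM/PSNR/OLS evaluation
tooling, plus NIfTI I/O and a small CLI
(`simulate | train | transfer | infer | evaluate`).

## Worked example

```r
library(qsmadapt)

# a synthetic susceptibility scene with a brain-like mask, and its field
# (the 32^3 recipe is calibrated to match the full-size scene statistics;
# see the methods vignette)
spec  <- shape_scene_spec(grid_shape = c(32, 32, 32),
                          rect_count_range = c(4, 8),
                          ellipsoid_count_range = c(10, 15),
                          polygon_count = 3, mask_ellipsoid_count = 40,
                          box_extent = c(0.05, 0.5),
                          ellipsoid_extent = c(0.025, 0.3),
                          polygon_radius = c(0.05, 0.375),
                          polygon_thickness = c(0.05, 0.375),
                          mask_ellipsoid_extent = c(0.1, 0.3))
scene <- sample_scene(spec, seed = 1502)
ex    <- make_training_example(scene)   # field, chi, side_info

# a miniature adaptive U-Net, pre-trained on 20 such scenes (~10 min CPU)
scenes <- lapply(1:20, function(i) sample_scene(spec, seed = 1000 + i))
model  <- build_adaptive_unet(adaptive_unet_spec(initial_channels = 8), seed = 1)
config <- train_run_config(epochs = 30, patch_size = 32, patches_per_volume = 1,
                           schedule = list(t0 = 30))
run    <- pretrain(model, scenes, config, seed = 1)

# invert the held-out field and score it
rec <- infer(ex$field, run$model)
metrics_report(rec$values, scene$values, scene$mask, seed = 1)
```

On this run the trained network prints

```
NRMSE 62.26%  SSIM 0.3422  PSNR 19.31 dB  slope 0.411  intercept -0.0021  (n=11475, seed=1)
```

while the untrained residual-identity network (whose output is just the
input field) scores

```
NRMSE 96.47%  SSIM 0.1240  PSNR 15.50 dB  slope 0.088  intercept -0.0051  (n=11475, seed=1)
```

The scaled-down model has learned a real, geometry-aware dipole inversion —
lower NRMSE, higher SSIM and an OLS slope pulled far up from the baseline's
— but a ten-minute CPU run sits nowhere near the published full-scale
reconstruction quality (SSIM ≈ 0.9 after multi-GPU training); it
underestimates susceptibility amplitudes (slope well below 1) and loses
fine structure.  The methods vignette quantifies what this budget does and
does not show.

For measured data, `read_volume()` extracts voxel size and B0 direction
from the NIfTI affine (B0 = scanner z-axis), both overridable:

```r
rec <- read_volume("localfield.nii.gz", b0_direction = c(-0.03, -0.42, 0.90))
chi <- infer(local_field_volume(rec$values, rec$geometry), run$model)
write_volume(chi, "chi.nii.gz")
```

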