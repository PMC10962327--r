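# Shared scaled-down training study used by the pre-training quality and
# smoke-optimization acceptance checks: 20 training scenes and 5 held-out
# scenes of 32^3 voxels, a miniature adaptive U-Net with 8 initial channels,
# 30 epochs of one 32^3 patch per scene, the reference optimizer/schedule
# settings (one cosine period over the run), lambda = 1 and the full
# augmentation set with geometry variation probability 0.8.  The scene
# recipe is calibrated so the scaled scenes match the statistics of the
# full-size recipe (nonzero coverage ~0.5-0.7, susceptibility sd ~0.11 ppm
# vs 0.13 at full size, masked fraction ~0.4): shape counts are reduced and
# shape extents enlarged as fractions of the grid.  The run executes once
# per test session and is reused across test blocks.

smoke_scene_spec <- function(grid = 32) {
  shape_scene_spec(grid_shape = rep(grid, 3),
                   rect_count_range = c(4, 8),
                   ellipsoid_count_range = c(10, 15),
                   polygon_count = 3,
                   mask_ellipsoid_count = 40,
                   box_extent = c(0.05, 0.5),
                   ellipsoid_extent = c(0.025, 0.3),
                   polygon_radius = c(0.05, 0.375),
                   polygon_thickness = c(0.05, 0.375),
                   mask_ellipsoid_extent = c(0.1, 0.3))
}

smoke_train_config <- function(epochs = 30, patch = 32) {
  train_run_config(epochs = epochs, patch_size = patch,
                   patches_per_volume = 1,
                   schedule = list(t0 = epochs, t_mult = 0.5,
                                   eta_init = 1e-3, eta_min = 1e-8))
}

# residual-identity reference: the untrained network with a zeroed final
# convolution, i.e. the map chi_hat = field
residual_identity_model <- function(seed = 1, channels = 8) {
  m <- build_adaptive_unet(adaptive_unet_spec(channels), seed = seed)
  cp <- qsmadapt:::collect_params(m)
  cp[["final_conv.w"]][] <- 0
  cp[["final_conv.b"]][] <- 0
  qsmadapt:::set_params(m, cp)
}

eval_on_scenes <- function(model, scenes, seed = 1) {
  res <- sapply(scenes, function(sc) {
    ex <- make_training_example(sc)
    rec <- infer(ex$field, model)
    c(ssim = ssim3d(rec$values, sc$values, sc$mask),
      slope = scatter_fit(rec$values, sc$values, sc$mask, n = 5000,
                          seed = seed)$slope,
      nrmse = nrmse(rec$values, sc$values, sc$mask))
  })
  rowMeans(res)
}

smoke_study <- local({
  cache <- NULL
  function(seed = 1) {
    if (!is.null(cache)) return(cache)
    spec <- smoke_scene_spec()
    train_scenes <- lapply(seq_len(20),
                           function(i) sample_scene(spec, seed = seed * 1000 + i))
    held_out <- lapply(seq_len(5),
                       function(i) sample_scene(spec, seed = seed * 1000 + 500 + i))
    model <- build_adaptive_unet(adaptive_unet_spec(8), seed = seed)
    run <- pretrain(model, train_scenes, smoke_train_config(), seed = seed)
    baseline <- residual_identity_model(seed = seed)
    cache <<- list(
      run = run,
      held_out = held_out,
      trained_metrics = eval_on_scenes(run$model, held_out, seed = seed),
      baseline_metrics = eval_on_scenes(baseline, held_out, seed = seed))
    cache
  }
})
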