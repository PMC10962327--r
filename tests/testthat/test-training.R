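test_that("the loss decomposes exactly and vanishes at ground truth", {
  set.seed(1)
  g <- acq_geometry(c(1, 1.2, 2), c(0.1, -0.1, 0.99))
  chi <- array(rnorm(8^3, sd = 0.2), c(8, 8, 8))
  b <- forward_field(chi, geometry = g)$values
  l0 <- model_loss(chi, chi, b, g, lambda = 1)
  expect_equal(l0$total, 0)
  expect_equal(l0$chi_term, 0)
  expect_equal(l0$field_term, 0)
  # lambda = 0 and a constant offset: mean-square of the constant
  lc <- model_loss(chi + 0.3, chi, b, g, lambda = 0)
  expect_equal(lc$total, 0.3^2)
  # additivity invariant holds for arbitrary reconstructions
  rec <- chi + array(rnorm(8^3, sd = 0.1), c(8, 8, 8))
  lr <- model_loss(rec, chi, b, g, lambda = 2.5)
  expect_identical(lr$total, lr$chi_term + 2.5 * lr$field_term)
  expect_true(lr$chi_term >= 0 && lr$field_term >= 0)
  expect_error(model_loss(rec, chi, b[1:4, 1:4, 1:4], g), "shape")
  expect_error(model_loss(rec, chi, b, g, lambda = -1), "lambda")
})

test_that("the loss agrees with an oracle-based recomputation", {
  set.seed(2)
  g <- acq_geometry(c(1.5, 1.5, 1), c(-0.05, 0.2, 0.97))
  chi_gt <- array(rnorm(8^3, sd = 0.25), c(8, 8, 8))
  chi_rec <- chi_gt + array(rnorm(8^3, sd = 0.05), c(8, 8, 8))
  b_gt <- forward_field_oracle(chi_gt, geometry = g)$values
  l <- model_loss(chi_rec, chi_gt, b_gt, g, lambda = 1)
  b_rec_oracle <- forward_field_oracle(chi_rec, geometry = g)$values
  ref <- mean((chi_rec - chi_gt)^2) + mean((b_gt - b_rec_oracle)^2)
  expect_equal(l$total, ref, tolerance = 1e-8)
  # sum mode gives plain squared L2 norms
  ls <- model_loss(chi_rec, chi_gt, b_gt, g, lambda = 1, norm = "sum")
  expect_equal(ls$total, l$total * length(chi_gt), tolerance = 1e-8)
})

test_that("cosine annealing with warm restarts hits the printed anchors", {
  expect_equal(schedule_lr(0), 1e-3)
  expect_equal(schedule_lr(250), (1e-3 + 1e-8) / 2, tolerance = 1e-12)
  expect_equal(schedule_lr(500), 1e-3)  # restart boundary
  expect_equal(schedule_lr(500 + 125), 1e-8 + 0.5 * (1e-3 - 1e-8) *
                 (1 + cos(pi / 2)), tolerance = 1e-12)
  # restart boundary after the first halved period
  expect_equal(schedule_lr(750), 1e-3)
  # shrinking periods floor at one epoch: with T0 = 2 the periods are
  # 2, 1, 1, ... so every integer step from 3 on restarts at eta_init
  expect_equal(schedule_lr(3, t0 = 2, t_mult = 0.5), 1e-3)
  expect_equal(schedule_lr(7, t0 = 2, t_mult = 0.5), 1e-3)
  expect_error(schedule_lr(-1), "step")
  expect_error(schedule_lr(1, t0 = 0), "periods")
})

small_training_setup <- function(n_scenes = 2, grid = 16) {
  spec <- shape_scene_spec(grid_shape = rep(grid, 3),
                           rect_count_range = c(2, 4),
                           ellipsoid_count_range = c(3, 6),
                           polygon_count = 1, mask_ellipsoid_count = 10)
  scenes <- lapply(seq_len(n_scenes), function(i) sample_scene(spec, seed = i))
  model <- build_adaptive_unet(
    adaptive_unet_spec(initial_channels = 2, levels = 2), seed = 1)
  config <- train_run_config(epochs = 2, patch_size = 16,
                             patches_per_volume = 1,
                             schedule = list(t0 = 2))
  list(scenes = scenes, model = model, config = config)
}

test_that("pre-training is reproducible and a zero-epoch run is the identity", {
  su <- small_training_setup()
  cfg0 <- su$config
  cfg0$epochs <- 0
  run0 <- pretrain(su$model, su$scenes, cfg0, seed = 3)
  expect_equal(qsmadapt:::collect_params(run0$model),
               qsmadapt:::collect_params(su$model))
  r1 <- pretrain(su$model, su$scenes, su$config, seed = 3)
  r2 <- pretrain(su$model, su$scenes, su$config, seed = 3)
  expect_identical(r1$history, r2$history)
  expect_identical(qsmadapt:::collect_params(r1$model),
                   qsmadapt:::collect_params(r2$model))
  r3 <- pretrain(su$model, su$scenes, su$config, seed = 4)
  expect_false(identical(r1$history, r3$history))
  expect_length(r1$history, 2)
  bad <- train_run_config(epochs = 1, patch_size = 64)
  expect_error(pretrain(su$model, su$scenes, bad, seed = 1), "patch")
})

test_that("transfer learning freezes the adaptive layer exactly", {
  su <- small_training_setup()
  paired <- lapply(su$scenes, function(sc) {
    ex <- make_training_example(sc)
    list(field = ex$field, chi = ex$chi, geometry = sc$geometry)
  })
  cfg <- su$config
  cfg$transfer$epochs <- 2
  cfg$transfer$patch_size <- 12
  cfg$transfer$pad_to <- 16
  before <- qsmadapt:::collect_params(su$model)
  run <- transfer_learn(su$model, paired, cfg, seed = 5)
  after <- qsmadapt:::collect_params(run$model)
  fmn_keys <- grep("\\.fmn\\.", names(before), value = TRUE)
  expect_gt(length(fmn_keys), 0)
  for (k in fmn_keys) expect_identical(before[[k]], after[[k]])
  expect_identical(before[["enc1_conv2.b"]], after[["enc1_conv2.b"]])
  # everything trainable did move
  expect_false(identical(before[["dec1_conv.w"]], after[["dec1_conv.w"]]))
  expect_false(identical(before[["enc1_conv1.w"]], after[["enc1_conv1.w"]]))
  # zero-epoch transfer is the identity on all parameters
  cfg$transfer$epochs <- 0
  run0 <- transfer_learn(su$model, paired, cfg, seed = 5)
  expect_equal(qsmadapt:::collect_params(run0$model), before)
})

test_that("the simulated-field branch satisfies the forward model by construction", {
  su <- small_training_setup(n_scenes = 1)
  sc <- su$scenes[[1]]
  g <- sc$geometry
  # with the simulated branch forced and unit scaling, input field and
  # susceptibility patches obey b = forward_field(chi) exactly
  chi_vals <- sc$values
  fld <- forward_field(chi_vals, geometry = g)$values
  expect_equal(fld, make_training_example(sc)$field$values)
  cfg <- su$config
  cfg$transfer$field_source_prob <- 0  # always the simulated branch
  cfg$transfer$scale_interval <- c(1, 1)
  cfg$transfer$epochs <- 1
  cfg$transfer$patch_size <- 16
  cfg$transfer$pad_to <- 16
  paired <- list(list(field = local_field_volume(fld * 0, g),  # decoy field
                      chi = susceptibility_volume(chi_vals, g),
                      geometry = g))
  run <- transfer_learn(su$model, paired, cfg, seed = 6)
  expect_length(run$history, 1)
  expect_true(is.finite(run$history))
})
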