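#' Physics-consistent training loss
#'
#' Combines a susceptibility fidelity term with a forward-model consistency
#' term: `L = L_chi + lambda * L_B`, where `L_chi` is the mean squared
#' difference between reconstructed and ground-truth susceptibility and
#' `L_B` the mean squared difference between the ground-truth field and the
#' field forward-simulated from the reconstruction under the acquisition
#' geometry.  The field term restricts optimization to solutions obeying the
#' dipole convolution model.  Mean (per-voxel) normalization is the default
#' so the loss scale is independent of the patch size; `norm = "sum"` gives
#' plain squared L2 norms.
#'
#' @param chi_rec,chi_gt 3D arrays (or volumes), reconstructed and
#'   ground-truth susceptibility in ppm.
#' @param b_gt 3D array (or volume), ground-truth local field in ppm.
#' @param geometry [acq_geometry()] used for the forward simulation.
#' @param lambda Non-negative field-term weight (the reference setting is 1).
#' @param norm `"mean"` or `"sum"`.
#' @return A `loss_breakdown` list: `total`, `chi_term`, `field_term`,
#'   `lambda`; `total == chi_term + lambda * field_term` exactly.
#' @export
model_loss <- function(chi_rec, chi_gt, b_gt, geometry, lambda = 1,
                       norm = c("mean", "sum")) {
  norm <- match.arg(norm)
  rec <- as_volume_values(chi_rec)
  gt <- as_volume_values(chi_gt)
  bg <- as_volume_values(b_gt)
  if (!identical(dim(rec), dim(gt)) || !identical(dim(rec), dim(bg))) {
    stop("loss inputs must share one shape")
  }
  if (lambda < 0) stop("lambda must be >= 0")
  red <- if (norm == "mean") mean else sum
  chi_term <- red((rec - gt)^2)
  b_rec <- forward_field(rec, geometry = geometry)$values
  field_term <- red((bg - b_rec)^2)
  structure(list(total = chi_term + lambda * field_term,
                 chi_term = chi_term, field_term = field_term,
                 lambda = lambda),
            class = "loss_breakdown")
}

# gradient of model_loss (mean norm) with respect to chi_rec; the dipole
# operator is self-adjoint (real, even kernel), so the field-term adjoint is
# another forward convolution
model_loss_grad <- function(chi_rec, chi_gt, b_gt, geometry, lambda = 1) {
  n <- length(chi_rec)
  resid_chi <- chi_rec - chi_gt
  b_rec <- forward_field(chi_rec, geometry = geometry)$values
  resid_b <- forward_field(b_rec - b_gt, geometry = geometry)$values
  (2 / n) * (resid_chi + lambda * resid_b)
}

#' Cosine-annealing learning rate with warm restarts
#'
#' Learning rate at a given (fractional) epoch under cosine annealing with
#' warm restarts: within a period of length `T_i` the rate decays from
#' `eta_init` to `eta_min` along a half cosine, then restarts at `eta_init`
#' with the next period `T_{i+1} = T_mult * T_i` (periods are floored at one
#' epoch, so a multiplier below 1 produces shrinking restart intervals until
#' they settle at one epoch).
#'
#' @param step Non-negative epoch position (may be fractional).
#' @param t0 First period length in epochs.
#' @param t_mult Period multiplier after each restart.
#' @param eta_init,eta_min Initial and floor learning rates.
#' @return Learning rate.
#' @examples
#' schedule_lr(0)             # 1e-3
#' schedule_lr(250)           # cosine midpoint of the first period
#' @export
schedule_lr <- function(step, t0 = 500, t_mult = 0.5, eta_init = 1e-3,
                        eta_min = 1e-8) {
  if (step < 0) stop("step must be >= 0")
  if (t0 < 1 || t_mult <= 0) stop("invalid schedule periods")
  ti <- max(1, t0)
  pos <- step
  while (pos >= ti) {
    pos <- pos - ti
    ti <- max(1, ti * t_mult)
  }
  eta_min + 0.5 * (eta_init - eta_min) * (1 + cos(pi * pos / ti))
}

#' Training run configuration
#'
#' Bundles the optimizer, schedule, patching and augmentation settings of a
#' training run.  Defaults are the reference settings: AdamW (beta1 0.9,
#' beta2 0.99, eps 1e-8, weight decay 0.01), cosine annealing with warm
#' restarts (T0 500, T_mult 0.5, eta 1e-3 down to 1e-8), lambda 1, four
#' patches of 160^3 per volume for pre-training over 500 epochs, and for
#' transfer learning 30 epochs of 96^3 patches zero-padded to 128^3 with the
#' adaptive layer frozen, decoder at learning rate 1e-3 and all other
#' parameters at 1e-5.
#'
#' @param epochs,patch_size,patches_per_volume Patch sampling plan.
#' @param lambda Field-term weight of [model_loss()].
#' @param optimizer List of AdamW settings.
#' @param schedule List of [schedule_lr()] settings.
#' @param augment List passed to [augment_patch()] options.
#' @param geometry_sampler A [geometry_sampler_spec()].
#' @param transfer List of transfer-learning settings: `field_source_prob`,
#'   `scale_interval`, `decoder_lr`, `other_lr`, `pad_to`, `mask_chi_term`.
#' @return A `train_run_config` list.
#' @export
train_run_config <- function(epochs = 500, patch_size = 160,
                             patches_per_volume = 4, lambda = 1,
                             optimizer = list(), schedule = list(),
                             augment = list(),
                             geometry_sampler = geometry_sampler_spec(),
                             transfer = list()) {
  opt <- utils::modifyList(list(beta1 = 0.9, beta2 = 0.99, eps = 1e-8,
                                weight_decay = 0.01), optimizer)
  sch <- utils::modifyList(list(t0 = 500, t_mult = 0.5, eta_init = 1e-3,
                                eta_min = 1e-8), schedule)
  tr <- utils::modifyList(list(field_source_prob = 0.5,
                               scale_interval = c(0, 2),
                               decoder_lr = 1e-3, other_lr = 1e-5,
                               epochs = 30, patch_size = 96, pad_to = 128,
                               mask_chi_term = FALSE), transfer)
  stopifnot(epochs >= 0, patch_size >= 1, patches_per_volume >= 1,
            lambda >= 0, tr$field_source_prob >= 0, tr$field_source_prob <= 1,
            tr$decoder_lr > 0, tr$other_lr > 0)
  structure(list(epochs = epochs, patch_size = as.integer(patch_size),
                 patches_per_volume = as.integer(patches_per_volume),
                 lambda = lambda, optimizer = opt, schedule = sch,
                 augment = augment, geometry_sampler = geometry_sampler,
                 transfer = tr),
            class = "train_run_config")
}

# ---- AdamW ----------------------------------------------------------------

adamw_init <- function(params) {
  list(t = 0,
       m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one decoupled-weight-decay Adam step; lr_by_key maps parameter keys to
# learning rates (0 or NA = frozen)
adamw_step <- function(params, grads, state, opt, lr_by_key) {
  state$t <- state$t + 1
  bc1 <- 1 - opt$beta1^state$t
  bc2 <- 1 - opt$beta2^state$t
  for (key in names(params)) {
    lr <- lr_by_key[[key]]
    if (is.null(lr) || is.na(lr) || lr == 0) next
    g <- grads[[key]]
    if (is.null(g)) next
    state$m[[key]] <- opt$beta1 * state$m[[key]] + (1 - opt$beta1) * g
    state$v[[key]] <- opt$beta2 * state$v[[key]] + (1 - opt$beta2) * g^2
    mh <- state$m[[key]] / bc1
    vh <- state$v[[key]] / bc2
    params[[key]] <- params[[key]] -
      lr * (mh / (sqrt(vh) + opt$eps) + opt$weight_decay * params[[key]])
  }
  list(params = params, state = state)
}

# draw a random patch corner for a patch of size ps from volume dims d
draw_patch_corner <- function(d, ps) {
  vapply(1:3, function(i) {
    if (d[i] <= ps) 1L else sample.int(d[i] - ps + 1L, 1)
  }, integer(1))
}

crop_patch <- function(vals, corner, ps) {
  vals[corner[1]:(corner[1] + ps - 1), corner[2]:(corner[2] + ps - 1),
       corner[3]:(corner[3] + ps - 1), drop = FALSE]
}

# gradient of the physics-consistent loss for one (field, chi, geometry)
# patch triple; the loss field term uses a patch-sized periodic dipole kernel
patch_grads <- function(model, field_patch, chi_patch, geometry, config) {
  fw <- unet_forward(model, field_patch, geometry$side_info, training = TRUE)
  n <- length(fw$y)
  b_gt <- forward_field(chi_patch, geometry = geometry)$values
  b_rec <- forward_field(fw$y, geometry = geometry)$values
  resid_chi <- fw$y - chi_patch
  resid_b <- b_rec - b_gt
  loss <- mean(resid_chi^2) + config$lambda * mean(resid_b^2)
  dy <- (2 / n) * (resid_chi + config$lambda *
                     forward_field(resid_b, geometry = geometry)$values)
  grads <- unet_backward(model, fw$cache, dy)
  list(grads = grads, loss = loss, buffers = fw$buffers)
}

# one AdamW step on the mean gradient over the patches cut from one volume
# (the patches of a volume form a batch, not separate steps)
train_step <- function(model, opt_state, patches, config, lr_by_key) {
  acc <- NULL
  losses <- numeric(length(patches))
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    pg <- patch_grads(model, p$field, p$chi, p$geometry, config)
    model$buffers <- pg$buffers
    losses[i] <- pg$loss
    if (is.null(acc)) {
      acc <- pg$grads
    } else {
      for (k in names(pg$grads)) acc[[k]] <- acc[[k]] + pg$grads[[k]]
    }
  }
  if (length(patches) > 1) {
    for (k in names(acc)) acc[[k]] <- acc[[k]] / length(patches)
  }
  upd <- adamw_step(collect_params(model), acc, opt_state, config$optimizer,
                    lr_by_key)
  model <- set_params(model, upd$params)
  list(model = model, opt_state = upd$state, loss = mean(losses))
}

# Recalibrate batch-norm running statistics with a forward sweep over
# freshly drawn training patches: running mean/var are replaced by the
# exact average of the per-patch batch statistics (cumulative-mean
# momentum), closing the gap between training-mode and inference-mode
# normalization.
recalibrate_bn <- function(model, scenes, config) {
  ps <- config$patch_size
  for (nm in names(model$buffers)) {
    model$buffers[[nm]]$rm[] <- 0
    model$buffers[[nm]]$rv[] <- 0
  }
  i <- 0
  for (scene in scenes) {
    geom <- sample_geometry(config$geometry_sampler,
                            seed = sample.int(2^31 - 1, 1))
    field <- forward_field(scene$values, geometry = geom)$values
    corner <- draw_patch_corner(dim(scene$values), ps)
    fld_p <- crop_patch(field, corner, ps)
    i <- i + 1
    model$bn_momentum <- 1 / i
    fw <- unet_forward(model, fld_p, geom$side_info, training = TRUE)
    model$buffers <- fw$buffers
  }
  model$bn_momentum <- NULL
  model
}

#' Pre-train a network on synthetic scenes
#'
#' Reference training loop: per epoch, every scene is paired with a freshly
#' sampled acquisition geometry (standard with probability `1 - p_var`), the
#' local field is forward-simulated on the full scene, `patches_per_volume`
#' patches are cut at random positions, augmented (joint scaling, flips and
#' 90-degree rotations of field and susceptibility; Gaussian noise on the
#' field input only), and one AdamW step under the cosine-annealing schedule
#' is taken per patch with the physics-consistent loss evaluated with a
#' patch-sized dipole kernel.  Fully reproducible given `(config, seed)`.
#'
#' @param model A `qsm_unet` (its current parameters are the starting point).
#' @param scenes List of [susceptibility_volume()] scenes.
#' @param config A [train_run_config()].
#' @param seed Integer seed controlling all randomness of the run.
#' @param verbose Print per-epoch losses.
#' @param recalibrate After training, replace the batch-norm running
#'   statistics by exact averages of per-patch batch statistics over one
#'   sweep of freshly drawn training patches, so inference-mode
#'   normalization matches what the network saw in training.
#' @return List: `model` (trained), `history` (per-epoch mean loss),
#'   `checkpoint` metadata fields.
#' @export
pretrain <- function(model, scenes, config = train_run_config(), seed = 1,
                     verbose = FALSE, recalibrate = TRUE) {
  stopifnot(inherits(model, "qsm_unet"), length(scenes) >= 1)
  ps <- config$patch_size
  for (sc in scenes) {
    if (any(dim(sc$values) < ps)) stop("patch larger than a training volume")
  }
  opt_state <- adamw_init(collect_params(model))
  all_keys <- names(collect_params(model))
  history <- numeric(0)
  with_local_seed(seed, {
    for (epoch in seq_len(config$epochs)) {
      lr <- schedule_lr(epoch - 1, config$schedule$t0, config$schedule$t_mult,
                        config$schedule$eta_init, config$schedule$eta_min)
      lr_by_key <- stats::setNames(as.list(rep(lr, length(all_keys))),
                                   all_keys)
      losses <- c()
      for (si in sample(seq_along(scenes))) {
        scene <- scenes[[si]]
        geom <- sample_geometry(config$geometry_sampler,
                                seed = sample.int(2^31 - 1, 1))
        field <- forward_field(scene$values, geometry = geom)$values
        patches <- lapply(seq_len(config$patches_per_volume), function(p) {
          corner <- draw_patch_corner(dim(scene$values), ps)
          chi_p <- crop_patch(scene$values, corner, ps)
          fld_p <- crop_patch(field, corner, ps)
          aug <- augment_patch(chi_p, options = utils::modifyList(
            list(noise = FALSE), config$augment))
          fld_aug <- augment_patch(fld_p, options = config$augment,
                                   params = aug$params)
          # flips/rotations tilt the effective B0 direction with the grid
          list(field = fld_aug$values, chi = aug$values,
               geometry = augment_geometry(geom, aug$params))
        })
        st <- train_step(model, opt_state, patches, config, lr_by_key)
        model <- st$model
        opt_state <- st$opt_state
        losses <- c(losses, st$loss)
      }
      history[epoch] <- mean(losses)
      if (verbose) {
        message(sprintf("epoch %d/%d  lr %.2e  loss %.5g", epoch,
                        config$epochs, lr, history[epoch]))
      }
    }
    if (recalibrate && config$epochs > 0) {
      model <- recalibrate_bn(model, scenes, config)
    }
  })
  list(model = model, history = history, seed = seed)
}

#' Transfer learning on paired field/susceptibility data
#'
#' Fine-tunes a pre-trained network on paired (measured field, ground-truth
#' susceptibility, geometry) items.  The adaptive layer (filter-manifold
#' network and its static bias) is frozen; decoder parameters train at
#' `transfer$decoder_lr`, all remaining parameters at `transfer$other_lr`.
#' Per item and patch, with probability `transfer$field_source_prob` the
#' stored measured field is used as input; otherwise the field is
#' forward-simulated from the susceptibility after scaling both by a factor
#' drawn uniformly from `transfer$scale_interval`.  Patches are zero-padded
#' to `transfer$pad_to` so the model sees border regions.
#'
#' @param model A pre-trained `qsm_unet`.
#' @param paired_data List of items, each a list with `field`
#'   ([local_field_volume()]), `chi` ([susceptibility_volume()]) and
#'   optionally `geometry`.
#' @param config A [train_run_config()]; the `transfer` sub-list applies.
#' @param seed Integer seed.
#' @param verbose Print per-epoch losses.
#' @return List: `model`, `history`.
#' @export
transfer_learn <- function(model, paired_data, config = train_run_config(),
                           seed = 1, verbose = FALSE) {
  stopifnot(inherits(model, "qsm_unet"), length(paired_data) >= 1)
  tr <- config$transfer
  ps <- tr$patch_size
  pad_to <- tr$pad_to
  stopifnot(pad_to >= ps)
  for (item in paired_data) {
    if (any(dim(item$chi$values) < ps)) {
      stop("transfer patch (", ps, "^3) larger than a training volume; ",
           "reduce config$transfer$patch_size")
    }
  }
  opt_state <- adamw_init(collect_params(model))
  dec_keys <- decoder_param_keys(model)
  frozen <- adaptive_param_keys(model)
  all_keys <- names(collect_params(model))
  lr_by_key <- stats::setNames(as.list(rep(tr$other_lr, length(all_keys))),
                               all_keys)
  lr_by_key[dec_keys] <- tr$decoder_lr
  lr_by_key[frozen] <- 0
  history <- numeric(0)
  with_local_seed(seed, {
    for (epoch in seq_len(tr$epochs)) {
      losses <- c()
      for (ii in sample(seq_along(paired_data))) {
        item <- paired_data[[ii]]
        geom <- item$geometry %||% item$chi$geometry
        patches <- lapply(seq_len(config$patches_per_volume), function(p) {
          use_measured <- runif(1) < tr$field_source_prob
          scale <- if (use_measured) 1 else
            runif(1, tr$scale_interval[1], tr$scale_interval[2])
          chi_vals <- item$chi$values * scale
          fld_vals <- if (use_measured) item$field$values else
            forward_field(chi_vals, geometry = geom)$values
          corner <- draw_patch_corner(dim(chi_vals), ps)
          list(field = zero_pad_to(crop_patch(fld_vals, corner, ps), pad_to),
               chi = zero_pad_to(crop_patch(chi_vals, corner, ps), pad_to),
               geometry = geom)
        })
        st <- train_step(model, opt_state, patches, config, lr_by_key)
        model <- st$model
        opt_state <- st$opt_state
        losses <- c(losses, st$loss)
      }
      history[epoch] <- mean(losses)
      if (verbose) {
        message(sprintf("transfer epoch %d/%d  loss %.5g", epoch, tr$epochs,
                        history[epoch]))
      }
    }
  })
  list(model = model, history = history, seed = seed)
}

zero_pad_to <- function(a, n) {
  d <- dim(a)
  if (all(d == n)) return(a)
  out <- array(0, rep(n, 3))
  off <- floor((n - d) / 2)
  out[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]), off[3] + seq_len(d[3])] <- a
  out
}
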