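#' Adaptive 3D U-Net specification
#'
#' Architecture of the field-to-susceptibility network: a standard 3D U-Net
#' with 16 initial channels, four encoder levels plus a bottleneck, two 3x3x3
#' convolutions per encoder block with channel doubling on the second
#' (1-16-32 | 32-32-64 | 64-64-128 | 128-128-256 | 256-256-256, the
#' bottleneck doubling capped), batch normalization and ELU after every
#' convolution, 2x2x2 max pooling, 2x2x2 transposed-convolution upsampling, a
#' thin decoder (fixed `decoder_channels` per level, one 3x3x3 convolution
#' after concatenation with the encoder skip), a final 3x3x3 convolution to
#' one channel, and a global input-to-output residual addition so the model
#' learns the difference between field perturbation and susceptibility.
#'
#' In the default `"adaptive"` variant the second convolution of the first
#' encoder block (16 -> 32 channels) takes its weights from a
#' filter-manifold network driven by the acquisition side information; the
#' `"conventional"` variant uses a static convolution there and ignores the
#' side information; the `"adaptive_encoder"` variant generates every
#' encoder and bottleneck convolution (10 layers) from its own FMN.
#'
#' @param initial_channels Channels after the first convolution (16).
#' @param levels Number of encoder resolution levels before the bottleneck.
#' @param decoder_channels Channels per decoder level (defaults to
#'   `initial_channels`).
#' @param fmn_hidden Hidden widths of each filter-manifold network.
#' @param variant `"adaptive"`, `"conventional"` or `"adaptive_encoder"`.
#' @return An `adaptive_unet_spec` list.
#' @export
adaptive_unet_spec <- function(initial_channels = 16, levels = 4,
                               decoder_channels = NULL,
                               fmn_hidden = c(12, 48, 196),
                               variant = c("adaptive", "conventional",
                                           "adaptive_encoder")) {
  variant <- match.arg(variant)
  if (is.null(decoder_channels)) decoder_channels <- initial_channels
  stopifnot(initial_channels >= 1, levels >= 1, decoder_channels >= 1)
  structure(list(initial_channels = as.integer(initial_channels),
                 levels = as.integer(levels),
                 decoder_channels = as.integer(decoder_channels),
                 fmn_hidden = as.integer(fmn_hidden),
                 variant = variant),
            class = "adaptive_unet_spec")
}

# conv-layer plan: name, in/out channels, and whether it sits in the encoder
unet_plan <- function(spec) {
  ic <- spec$initial_channels
  L <- spec$levels
  dch <- spec$decoder_channels
  convs <- list()
  add <- function(name, cin, cout, kind = "conv3", encoder = FALSE) {
    convs[[name]] <<- list(name = name, cin = cin, cout = cout, kind = kind,
                           encoder = encoder)
  }
  cin <- 1L
  for (l in seq_len(L)) {
    c1 <- ic * 2L^(l - 1L)
    add(paste0("enc", l, "_conv1"), cin, c1, encoder = TRUE)
    add(paste0("enc", l, "_conv2"), c1, 2L * c1, encoder = TRUE)
    cin <- 2L * c1
  }
  cap <- cin  # bottleneck channel doubling capped at the encoder maximum
  add("bot_conv1", cin, cap, encoder = TRUE)
  add("bot_conv2", cap, cap, encoder = TRUE)
  prev <- cap
  for (l in rev(seq_len(L))) {
    skip <- ic * 2L^l
    add(paste0("dec", l, "_up"), prev, dch, kind = "up2")
    add(paste0("dec", l, "_conv"), dch + skip, dch)
    prev <- dch
  }
  add("final_conv", dch, 1L)
  convs
}

adaptive_layer_names <- function(spec) {
  switch(spec$variant,
         adaptive = "enc1_conv2",
         conventional = character(0),
         adaptive_encoder = {
           nm <- unlist(lapply(seq_len(spec$levels), function(l)
             paste0("enc", l, c("_conv1", "_conv2"))))
           c(nm, "bot_conv1", "bot_conv2")
         })
}

#' Build the adaptive 3D U-Net
#'
#' Initializes all parameters (He initialization for static convolutions,
#' zero-centred batch-norm scales at 1) and the filter-manifold network(s)
#' for the requested variant.  `build_conventional_unet()` and
#' `build_adaptive_encoder_unet()` are conveniences fixing the variant.
#'
#' @param spec An [adaptive_unet_spec()].
#' @param seed Integer seed for reproducible initialization.
#' @return Object of class `qsm_unet` holding `spec`, `params` (static
#'   weights), `fmns` (filter-manifold networks by layer name) and `buffers`
#'   (batch-norm running statistics).
#' @export
build_adaptive_unet <- function(spec = adaptive_unet_spec(), seed = 1) {
  stopifnot(inherits(spec, "adaptive_unet_spec"))
  plan <- unet_plan(spec)
  adaptive <- adaptive_layer_names(spec)
  with_local_seed(seed, {
    params <- list()
    buffers <- list()
    fmns <- list()
    for (cv in plan) {
      nm <- cv$name
      if (cv$kind == "conv3") {
        if (nm %in% adaptive) {
          kd <- c(cv$cout, cv$cin, 3L, 3L, 3L)
          fmns[[nm]] <- build_fmn(
            filter_manifold_spec(6, spec$fmn_hidden, kd),
            seed = sample.int(2^31 - 1, 1))
          params[[nm]] <- list(b = numeric(cv$cout))
        } else if (nm == "final_conv") {
          # zero start: the network begins as the residual identity, so the
          # correction branch grows from zero instead of drowning the
          # ppm-scale target in initialization noise
          params[[nm]] <- list(w = array(0, c(cv$cout, cv$cin, 3, 3, 3)),
                               b = numeric(cv$cout))
        } else {
          fan_in <- 27 * cv$cin
          params[[nm]] <- list(
            w = array(rnorm(cv$cout * cv$cin * 27, 0, sqrt(2 / fan_in)),
                      c(cv$cout, cv$cin, 3, 3, 3)),
            b = numeric(cv$cout))
        }
      } else {  # up2 transposed conv, kernel (cin, cout, 2, 2, 2)
        fan_in <- cv$cin  # each output voxel sees one input voxel per channel
        params[[nm]] <- list(
          w = array(rnorm(cv$cin * cv$cout * 8, 0, sqrt(2 / fan_in)),
                    c(cv$cin, cv$cout, 2, 2, 2)),
          b = numeric(cv$cout))
      }
      if (nm != "final_conv") {
        bn <- paste0(nm, "_bn")
        params[[bn]] <- list(gamma = rep(1, cv$cout), beta = numeric(cv$cout))
        buffers[[bn]] <- list(rm = numeric(cv$cout), rv = rep(1, cv$cout))
      }
    }
    structure(list(spec = spec, plan = plan, params = params, fmns = fmns,
                   buffers = buffers, adaptive = adaptive),
              class = "qsm_unet")
  })
}

#' @rdname build_adaptive_unet
#' @param ... Passed to [adaptive_unet_spec()].
#' @export
build_conventional_unet <- function(..., seed = 1) {
  build_adaptive_unet(adaptive_unet_spec(..., variant = "conventional"), seed)
}

#' @rdname build_adaptive_unet
#' @export
build_adaptive_encoder_unet <- function(..., seed = 1) {
  build_adaptive_unet(adaptive_unet_spec(..., variant = "adaptive_encoder"),
                      seed)
}

#' @export
print.qsm_unet <- function(x, ...) {
  cat(sprintf("Adaptive 3D U-Net (%s): %d initial channels, %d levels, %s trainable parameters, %d adaptive layer(s)\n",
              x$spec$variant, x$spec$initial_channels, x$spec$levels,
              format(count_parameters(x), big.mark = ","),
              length(x$adaptive)))
  invisible(x)
}

#' Count trainable parameters
#'
#' Total number of trainable scalars: static convolution weights and biases,
#' batch-norm scales and shifts, and all filter-manifold network parameters.
#'
#' @param model A `qsm_unet` (or `fmn`) object.
#' @return Integer count.
#' @export
count_parameters <- function(model) {
  sum(vapply(collect_params(model), length, numeric(1)))
}

# flatten all trainable parameters into a named list of arrays
collect_params <- function(model) {
  if (inherits(model, "fmn")) {
    out <- model$params
    names(out) <- paste0("fmn.", names(out))
    return(out)
  }
  out <- list()
  for (nm in names(model$params)) {
    for (pn in names(model$params[[nm]])) {
      out[[paste0(nm, ".", pn)]] <- model$params[[nm]][[pn]]
    }
  }
  for (nm in names(model$fmns)) {
    fp <- model$fmns[[nm]]$params
    for (pn in names(fp)) out[[paste0(nm, ".fmn.", pn)]] <- fp[[pn]]
  }
  out
}

set_params <- function(model, flat) {
  for (key in names(flat)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) == 3 && parts[2] == "fmn") {
      model$fmns[[parts[1]]]$params[[parts[3]]] <- flat[[key]]
    } else {
      model$params[[parts[1]]][[parts[2]]] <- flat[[key]]
    }
  }
  model
}

# parameter keys belonging to the decoding branch
decoder_param_keys <- function(model) {
  keys <- names(collect_params(model))
  keys[grepl("^(dec|final_conv)", keys)]
}

# parameter keys of the adaptive layer(s): FMN weights plus the static bias
adaptive_param_keys <- function(model) {
  if (!length(model$adaptive)) return(character(0))
  keys <- names(collect_params(model))
  pat <- paste0("^(", paste(model$adaptive, collapse = "|"), ")\\.")
  keys[grepl(pat, keys)]
}

divisibility <- function(spec) 2L^spec$levels

# ---- forward / backward ---------------------------------------------------

bn_stats <- function(x) {
  d <- dim(x)
  m <- matrix(x, prod(d[1:3]), d[4])
  mu <- colMeans(m)
  va <- colMeans(m^2) - mu^2
  list(mu = mu, va = pmax(va, 0))
}

sweep_channels <- function(x, v, op = "-") {
  d <- dim(x)
  sweep(x, 4, v, op)
}

#' Forward pass of the U-Net
#'
#' Maps a local-field patch and side-information vector to a susceptibility
#' patch of identical shape.  Spatial dimensions must be divisible by
#' `2^levels`; [infer()] handles padding for arbitrary volumes.
#'
#' @param model A `qsm_unet`.
#' @param x 3D array (or `(X, Y, Z, 1)`), the local field patch in ppm.
#' @param s Side-information vector (ignored by the conventional variant).
#' @param training Use batch statistics and keep caches for
#'   [unet_backward()]; otherwise running statistics, no cache.
#' @return List with `y` (3D array) and, when training, `cache`.
#' @export
unet_forward <- function(model, x, s = c(1, 1, 1, 0, 0, 1), training = FALSE) {
  x <- as.array(x)
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  dv <- divisibility(model$spec)
  if (any(dim(x)[1:3] %% dv != 0)) {
    stop(sprintf("spatial dims must be divisible by %d; pad the input", dv))
  }
  eps <- 1e-5
  momentum <- model$bn_momentum %||% 0.1
  cache <- if (training) new.env(parent = emptyenv()) else NULL
  st <- function(nm, val) if (training) assign(nm, val, envir = cache)

  conv_fw <- function(nm, h) {
    p <- model$params[[nm]]
    if (nm %in% model$adaptive) {
      fk <- fmn_forward(model$fmns[[nm]], s, with_cache = training)
      w <- if (training) fk$kernel else fk
      if (training) st(paste0(nm, ".fmncache"), fk$cache)
    } else {
      w <- p$w
    }
    st(paste0(nm, ".x"), h)
    st(paste0(nm, ".w"), w)
    conv3d_forward_cpp(h, w, p$b)
  }
  up_fw <- function(nm, h) {
    p <- model$params[[nm]]
    st(paste0(nm, ".x"), h)
    convtranspose3d_forward_cpp(h, p$w, p$b)
  }
  bn_fw <- function(nm, h) {
    p <- model$params[[nm]]
    if (training) {
      s2 <- bn_stats(h)
      model$buffers[[nm]]$rm <<- (1 - momentum) * model$buffers[[nm]]$rm +
        momentum * s2$mu
      model$buffers[[nm]]$rv <<- (1 - momentum) * model$buffers[[nm]]$rv +
        momentum * s2$va
    } else {
      s2 <- list(mu = model$buffers[[nm]]$rm, va = model$buffers[[nm]]$rv)
    }
    inv <- 1 / sqrt(s2$va + eps)
    xhat <- sweep_channels(sweep_channels(h, s2$mu), inv, "*")
    st(paste0(nm, ".xhat"), xhat)
    st(paste0(nm, ".inv"), inv)
    sweep_channels(sweep_channels(xhat, p$gamma, "*"), p$beta, "+")
  }
  act_fw <- function(nm, h) {
    st(paste0(nm, ".a"), h)
    elu(h)
  }
  block <- function(nm, h) act_fw(nm, bn_fw(paste0(nm, "_bn"), conv_fw(nm, h)))

  h <- x
  skips <- list()
  pools <- list()
  for (l in seq_len(model$spec$levels)) {
    h <- block(paste0("enc", l, "_conv1"), h)
    h <- block(paste0("enc", l, "_conv2"), h)
    skips[[l]] <- h
    mp <- maxpool3d_forward_cpp(h)
    st(paste0("pool", l, ".argmax"), mp$argmax)
    st(paste0("pool", l, ".indim"), dim(h))
    h <- mp$y
  }
  h <- block("bot_conv1", h)
  h <- block("bot_conv2", h)
  for (l in rev(seq_len(model$spec$levels))) {
    nm <- paste0("dec", l, "_up")
    h <- act_fw(nm, bn_fw(paste0(nm, "_bn"), up_fw(nm, h)))
    d1 <- dim(h)[4]
    h <- abind4(h, skips[[l]])
    st(paste0("cat", l, ".split"), d1)
    h <- block(paste0("dec", l, "_conv"), h)
  }
  yc <- conv_fw("final_conv", h)
  y <- x + yc
  out <- list(y = array(y, dim(y)[1:3]))
  if (training) out$cache <- cache
  # propagate buffer updates (model copied by value otherwise)
  out$buffers <- model$buffers
  out
}

abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

#' Backward pass of the U-Net
#'
#' Backpropagates a gradient with respect to the output through the whole
#' network (including the filter-manifold network of adaptive layers).
#'
#' @param model The `qsm_unet` used in the forward pass.
#' @param cache Cache returned by `unet_forward(..., training = TRUE)`.
#' @param dy Gradient array, same spatial shape as the output.
#' @return Named flat list of parameter gradients (keys as in the internal
#'   flat parameter representation).
#' @export
unet_backward <- function(model, cache, dy) {
  dy <- as.array(dy)
  if (length(dim(dy)) == 3) dim(dy) <- c(dim(dy), 1L)
  grads <- list()
  gv <- function(nm) get(nm, envir = cache)

  conv_bw <- function(nm, d) {
    x <- gv(paste0(nm, ".x"))
    w <- gv(paste0(nm, ".w"))
    bk <- conv3d_backward_cpp(x, w, d)
    if (nm %in% model$adaptive) {
      fg <- fmn_backward(model$fmns[[nm]], gv(paste0(nm, ".fmncache")), bk$dw)
      fg$ds <- NULL
      for (pn in names(fg)) grads[[paste0(nm, ".fmn.", pn)]] <<- fg[[pn]]
    } else {
      grads[[paste0(nm, ".w")]] <<- bk$dw
    }
    grads[[paste0(nm, ".b")]] <<- bk$db
    bk$dx
  }
  up_bw <- function(nm, d) {
    x <- gv(paste0(nm, ".x"))
    bk <- convtranspose3d_backward_cpp(x, model$params[[nm]]$w, d)
    grads[[paste0(nm, ".w")]] <<- bk$dw
    grads[[paste0(nm, ".b")]] <<- bk$db
    bk$dx
  }
  bn_bw <- function(nm, d) {
    p <- model$params[[nm]]
    xhat <- gv(paste0(nm, ".xhat"))
    inv <- gv(paste0(nm, ".inv"))
    dd <- dim(d)
    N <- prod(dd[1:3])
    dm <- matrix(d, N, dd[4])
    xm <- matrix(xhat, N, dd[4])
    grads[[paste0(nm, ".gamma")]] <<- colSums(dm * xm)
    grads[[paste0(nm, ".beta")]] <<- colSums(dm)
    dxh <- sweep_channels(d, p$gamma, "*")
    dxm <- matrix(dxh, N, dd[4])
    t1 <- colSums(dxm)
    t2 <- colSums(dxm * xm)
    dx <- sweep_channels(
      dxh - sweep_channels(array(rep(1, length(d)), dd), t1 / N, "*") -
        sweep_channels(xhat, t2 / N, "*"),
      inv, "*")
    dx
  }
  act_bw <- function(nm, d) d * elu_grad(gv(paste0(nm, ".a")))
  block_bw <- function(nm, d) {
    conv_bw(nm, bn_bw(paste0(nm, "_bn"), act_bw(nm, d)))
  }

  d <- conv_bw("final_conv", dy)  # residual: dy also reaches the input
  for (l in seq_len(model$spec$levels)) {
    d <- block_bw(paste0("dec", l, "_conv"), d)
    n1 <- gv(paste0("cat", l, ".split"))
    dup <- d[, , , seq_len(n1), drop = FALSE]
    dskip <- d[, , , -seq_len(n1), drop = FALSE]
    nm <- paste0("dec", l, "_up")
    d <- up_bw(nm, bn_bw(paste0(nm, "_bn"), act_bw(nm, dup)))
    # gradient entering the encoder skip for this level
    assign(paste0("skipgrad", l), dskip, envir = cache)
  }
  d <- block_bw("bot_conv1", block_bw("bot_conv2", d))
  for (l in rev(seq_len(model$spec$levels))) {
    d <- maxpool3d_backward_cpp(d, gv(paste0("pool", l, ".argmax")),
                                gv(paste0("pool", l, ".indim")))
    d <- d + gv(paste0("skipgrad", l))
    d <- block_bw(paste0("enc", l, "_conv2"), d)
    d <- block_bw(paste0("enc", l, "_conv1"), d)
  }
  grads
}

# ---- inference ------------------------------------------------------------

pad_reflect_to <- function(a, target) {
  d <- dim(a)
  idx <- lapply(1:3, function(i) {
    n <- d[i]; t <- target[i]
    if (t == n) return(seq_len(n))
    extra <- t - n
    # mirror without repeating the edge sample
    refl <- rev(seq_len(n))[seq_len(min(extra, n - 1)) + 1]
    c(seq_len(n), refl, rep(1L, max(0, extra - (n - 1))))
  })
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Apply a trained network to a local-field volume
#'
#' Pads the volume by reflection to the divisibility constraint of the
#' network, runs the forward pass in inference mode with the volume's
#' side information, crops back, and applies the mask if present.
#'
#' @param field A [local_field_volume()] carrying its acquisition geometry,
#'   or a bare 3D array (then `geometry` is required).
#' @param model A `qsm_unet` or a checkpoint loaded via [load_checkpoint()].
#' @param geometry Geometry override; required for bare arrays.
#' @return A [susceptibility_volume()] of the input shape.
#' @export
infer <- function(field, model, geometry = NULL) {
  if (inherits(field, "qsm_volume")) {
    if (is.null(geometry)) geometry <- field$geometry
    vals <- field$values
    mask <- field$mask
  } else {
    if (is.null(geometry)) {
      stop("no acquisition geometry: pass a local_field_volume or supply ",
           "`geometry` with voxel size (--voxel-size) and B0 direction (--b0-dir)")
    }
    vals <- as.array(field)
    mask <- NULL
  }
  stopifnot_geometry(geometry)
  if (inherits(model, "qsm_checkpoint")) model <- checkpoint_model(model)
  dv <- divisibility(model$spec)
  d0 <- dim(vals)
  target <- as.integer(ceiling(d0 / dv) * dv)
  padded <- pad_reflect_to(vals, target)
  out <- unet_forward(model, padded, geometry$side_info, training = FALSE)
  y <- out$y[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3])]
  if (!is.null(mask)) y <- y * mask
  susceptibility_volume(y, geometry, mask)
}

# ---- checkpoints ----------------------------------------------------------

spec_fingerprint <- function(spec) {
  paste(deparse(unclass(spec), control = "all"), collapse = "")
}

#' Save and load model checkpoints
#'
#' A checkpoint stores all trainable parameters, the batch-norm running
#' statistics, a fingerprint of the architecture spec and free-form training
#' metadata (epoch, seed, config hash).  Loading refuses a checkpoint whose
#' fingerprint does not match the requested architecture.
#'
#' @param model A `qsm_unet`.
#' @param path File path (RDS serialization).
#' @param metadata Named list of run metadata.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a `qsm_checkpoint`; `checkpoint_model` materializes the model.
#' @export
save_checkpoint <- function(model, path, metadata = list()) {
  ck <- structure(list(spec = model$spec,
                       fingerprint = spec_fingerprint(model$spec),
                       params = collect_params(model),
                       buffers = model$buffers,
                       metadata = metadata),
                  class = "qsm_checkpoint")
  saveRDS(ck, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param expect_spec Optional [adaptive_unet_spec()] the checkpoint must
#'   match.
#' @export
load_checkpoint <- function(path, expect_spec = NULL) {
  ck <- readRDS(path)
  if (!inherits(ck, "qsm_checkpoint")) stop("not a qsm checkpoint: ", path)
  if (!identical(ck$fingerprint, spec_fingerprint(ck$spec))) {
    stop("checkpoint fingerprint does not match its own spec; file corrupt?")
  }
  if (!is.null(expect_spec) &&
      !identical(spec_fingerprint(expect_spec), ck$fingerprint)) {
    stop("checkpoint architecture does not match the requested spec")
  }
  ck
}

#' @rdname save_checkpoint
#' @param checkpoint A `qsm_checkpoint`.
#' @export
checkpoint_model <- function(checkpoint) {
  stopifnot(inherits(checkpoint, "qsm_checkpoint"))
  model <- build_adaptive_unet(checkpoint$spec, seed = 1)
  model <- set_params(model, checkpoint$params)
  model$buffers <- checkpoint$buffers
  model
}
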