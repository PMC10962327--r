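#' Filter-manifold network specification
#'
#' The filter-manifold network (FMN) is a small fully connected feed-forward
#' network that maps the six-component side-information vector (voxel size
#' and B0 orientation) to the weights of a 3D convolution kernel.  Hidden
#' widths increase gradually; the final linear layer emits exactly
#' `prod(kernel_dim)` values that are reshaped into the rank-5 weight tensor
#' (out-channels, in-channels, 3, 3, 3).  With the default placement (first
#' encoder block of a 16-channel U-Net, 16 -> 32 channels) the final layer
#' encodes 13,824 kernel values.
#'
#' @param input_size Length of the side-information vector (6).
#' @param hidden_sizes Strictly increasing hidden-layer widths.
#' @param kernel_dim Output kernel dimensions `(out, in, 3, 3, 3)`.
#' @return A `filter_manifold_spec` list with an `output_size` field.
#' @export
filter_manifold_spec <- function(input_size = 6,
                                 hidden_sizes = c(12, 48, 196),
                                 kernel_dim = c(32, 16, 3, 3, 3)) {
  hidden_sizes <- as.integer(hidden_sizes)
  kernel_dim <- as.integer(kernel_dim)
  if (any(diff(hidden_sizes) <= 0)) {
    stop("hidden sizes must be strictly increasing")
  }
  if (length(kernel_dim) != 5) stop("kernel_dim must have 5 components")
  structure(list(input_size = as.integer(input_size),
                 hidden_sizes = hidden_sizes,
                 kernel_dim = kernel_dim,
                 output_size = prod(kernel_dim)),
            class = "filter_manifold_spec")
}

#' Build a filter-manifold network
#'
#' Initializes the four affine layers (input -> hidden1 -> hidden2 ->
#' hidden3 -> kernel values) with ELU activations between hidden layers and
#' a linear final layer.  The final layer starts with near-zero weights and a
#' bias drawn at the scale of a conventionally initialized convolution
#' kernel, so the generated kernel begins close to a static initialization
#' and moves smoothly with the side information as training proceeds.
#'
#' @param spec A [filter_manifold_spec()].
#' @param seed Integer seed for reproducible initialization.
#' @return Object of class `fmn`: `spec` plus a flat list of parameter
#'   matrices/vectors `W1, b1, ..., W4, b4`.
#' @export
build_fmn <- function(spec = filter_manifold_spec(), seed = 1) {
  stopifnot(inherits(spec, "filter_manifold_spec"))
  widths <- c(spec$input_size, spec$hidden_sizes, spec$output_size)
  with_local_seed(seed, {
    params <- list()
    for (i in seq_len(4)) {
      fan_in <- widths[i]
      fan_out <- widths[i + 1]
      if (i < 4) {
        params[[paste0("W", i)]] <-
          matrix(rnorm(fan_out * fan_in, 0, sqrt(2 / fan_in)), fan_out, fan_in)
        params[[paste0("b", i)]] <- numeric(fan_out)
      } else {
        # near-zero weights + conv-scale bias: w(s) starts near a static init
        conv_fan_in <- prod(spec$kernel_dim[c(2, 3, 4, 5)])
        params[[paste0("W", i)]] <-
          matrix(rnorm(fan_out * fan_in, 0, 1e-3), fan_out, fan_in)
        params[[paste0("b", i)]] <-
          rnorm(fan_out, 0, sqrt(2 / conv_fan_in))
      }
    }
    structure(list(spec = spec, params = params), class = "fmn")
  })
}

elu <- function(x) pmax(x, 0) + expm1(pmin(x, 0))
elu_grad <- function(x) exp(pmin(x, 0))

#' Generate the convolution kernel for a side-information vector
#'
#' @param fmn An [build_fmn()] object.
#' @param s Numeric side-information vector of length `spec$input_size`.
#' @param with_cache Keep pre-activations for [fmn_backward()].
#' @return The rank-5 kernel array `(out, in, 3, 3, 3)`; with
#'   `with_cache = TRUE`, a list `kernel`, `cache`.
#' @export
fmn_forward <- function(fmn, s, with_cache = FALSE) {
  stopifnot(inherits(fmn, "fmn"))
  s <- as.numeric(s)
  if (length(s) != fmn$spec$input_size) {
    stop("side information must have length ", fmn$spec$input_size)
  }
  p <- fmn$params
  a1 <- drop(p$W1 %*% s) + p$b1
  h1 <- elu(a1)
  a2 <- drop(p$W2 %*% h1) + p$b2
  h2 <- elu(a2)
  a3 <- drop(p$W3 %*% h2) + p$b3
  h3 <- elu(a3)
  out <- drop(p$W4 %*% h3) + p$b4
  kernel <- array(out, fmn$spec$kernel_dim)
  if (!with_cache) return(kernel)
  list(kernel = kernel,
       cache = list(s = s, a1 = a1, h1 = h1, a2 = a2, h2 = h2,
                    a3 = a3, h3 = h3))
}

#' Backpropagate a kernel gradient through the FMN
#'
#' @param fmn An `fmn` object.
#' @param cache Cache from `fmn_forward(..., with_cache = TRUE)`.
#' @param dkernel Gradient with respect to the generated kernel (same dims).
#' @return List of gradients named like the FMN parameters, plus `ds`.
#' @export
fmn_backward <- function(fmn, cache, dkernel) {
  p <- fmn$params
  dout <- as.numeric(dkernel)
  g <- list()
  g$W4 <- outer(dout, cache$h3)
  g$b4 <- dout
  dh3 <- drop(crossprod(p$W4, dout))
  da3 <- dh3 * elu_grad(cache$a3)
  g$W3 <- outer(da3, cache$h2)
  g$b3 <- da3
  dh2 <- drop(crossprod(p$W3, da3))
  da2 <- dh2 * elu_grad(cache$a2)
  g$W2 <- outer(da2, cache$h1)
  g$b2 <- da2
  dh1 <- drop(crossprod(p$W2, da2))
  da1 <- dh1 * elu_grad(cache$a1)
  g$W1 <- outer(da1, cache$s)
  g$b1 <- da1
  g$ds <- drop(crossprod(p$W1, da1))
  g
}

#' Adaptive convolution forward pass
#'
#' Convolves a feature map with the kernel generated by the FMN for the given
#' side information (3x3x3, same-size zero padding), plus a static per-output
#' channel bias.
#'
#' @param x Feature map array `(X, Y, Z, channels)`; channels must equal the
#'   kernel's in-channels.
#' @param s Side-information vector.
#' @param fmn An `fmn` object.
#' @param bias Optional numeric vector of out-channel biases (default zeros).
#' @return Feature map `(X, Y, Z, out_channels)`.
#' @export
adaptive_forward <- function(x, s, fmn, bias = NULL) {
  x <- as.array(x)
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  kd <- fmn$spec$kernel_dim
  if (dim(x)[4] != kd[2]) {
    stop(sprintf("feature map has %d channels but the kernel expects %d",
                 dim(x)[4], kd[2]))
  }
  w <- fmn_forward(fmn, s)
  if (is.null(bias)) bias <- numeric(kd[1])
  conv3d_forward_cpp(x, w, bias)
}

#' Sensitivity of the generated kernel to side information
#'
#' Finite-difference measure `||w(s + delta) - w(s)|| / ||delta||` used to
#' inspect how strongly the filter manifold responds to a change in
#' acquisition parameters.
#'
#' @param fmn An `fmn` object.
#' @param s Side-information vector.
#' @param delta Non-zero perturbation vector of the same length.
#' @return Non-negative scalar.
#' @export
kernel_sensitivity <- function(fmn, s, delta) {
  delta <- as.numeric(delta)
  nd <- sqrt(sum(delta^2))
  if (nd == 0) stop("delta must be non-zero")
  w0 <- fmn_forward(fmn, s)
  w1 <- fmn_forward(fmn, as.numeric(s) + delta)
  sqrt(sum((w1 - w0)^2)) / nd
}
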