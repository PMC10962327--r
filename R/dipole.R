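#' Unit dipole response in k-space
#'
#' Builds the k-space dipole kernel d(k) = 1/3 - (k . o)^2 / |k|^2 on the
#' discrete frequency grid of a volume with the given voxel size and B0
#' orientation.  The kernel vanishes on the conical surface at the magic
#' angle (arccos(1/sqrt(3)), about 54.7 degrees between k and the field
#' direction), which is what makes field-to-susceptibility inversion
#' ill-posed.  Anisotropic voxels enter through the per-axis frequency
#' scaling 1/(N_i * v_i); a tilted field of view enters only through the
#' projection of k onto the unit field direction.
#'
#' @param shape Integer length-3 grid dimensions (each >= 2).
#' @param geometry An [acq_geometry()].
#' @param dc_convention Value assigned at k = 0 where the ratio is undefined.
#'   The default 0 fixes the arbitrary field offset, consistent with
#'   referencing susceptibility maps to their mean.
#' @return Object of class `dipole_kernel`: list with `values` (3D array in
#'   unshifted FFT layout), `shape`, `geometry`, `dc_convention`.
#' @examples
#' k <- build_dipole_kernel(c(8, 8, 8), acq_geometry())
#' range(k$values[-1]) # within [-2/3, 1/3]
#' @export
build_dipole_kernel <- function(shape, geometry = acq_geometry(),
                                dc_convention = 0) {
  stopifnot_geometry(geometry)
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 2)) {
    stop("shape must be 3 integers >= 2")
  }
  f <- lapply(1:3, function(i) {
    fft_freqs(shape[i]) / geometry$voxel_size[i]
  })
  o <- geometry$b0_direction
  kx <- array(f[[1]], shape)
  ky <- array(rep(f[[2]], each = shape[1]), shape)
  kz <- array(rep(f[[3]], each = shape[1] * shape[2]), shape)
  k2 <- kx^2 + ky^2 + kz^2
  kzp <- kx * o[1] + ky * o[2] + kz * o[3]
  d <- 1 / 3 - kzp^2 / k2
  # symmetrize at the Nyquist planes of even-sized axes: the unpaired
  # frequency -N/2 breaks the evenness of (k.o)^2 for oblique o; averaging
  # d(k) with d(-k mod N) keeps the convolution operator exactly real and
  # self-adjoint on the discrete grid
  if (any(shape %% 2 == 0)) {
    neg <- lapply(shape, function(n) c(1, n:2))
    d <- (d + d[neg[[1]], neg[[2]], neg[[3]]]) / 2
  }
  d[1, 1, 1] <- dc_convention
  structure(list(values = d, shape = shape, geometry = geometry,
                 dc_convention = dc_convention),
            class = "dipole_kernel")
}

# signed discrete frequencies in cycles per voxel-unit, unshifted FFT order
fft_freqs <- function(n) {
  half <- floor((n - 1) / 2)
  c(0:half, -(n - half - 1):-1) / n
}

#' Forward field simulation from a susceptibility distribution
#'
#' Computes the relative magnetic field perturbation (ppm at the reference
#' field) induced by a susceptibility volume via multiplication with the
#' k-space dipole kernel: B = F^-1\{ d(k) F\{chi\} \}.  The operation is
#' linear in chi and periodic in space (circular convolution); `pad = TRUE`
#' zero-pads each axis to twice its size before the transform to suppress
#' wrap-around in validation runs.
#'
#' @param chi A [susceptibility_volume()] (or bare 3D array, in which case
#'   `geometry` must be supplied).
#' @param geometry Geometry override when `chi` is a bare array.
#' @param dc_convention Passed to [build_dipole_kernel()].
#' @param pad Zero-pad 2x to approximate an aperiodic convolution.
#' @return A [local_field_volume()] with the same shape, geometry and mask.
#' @export
forward_field <- function(chi, geometry = NULL, dc_convention = 0,
                          pad = FALSE) {
  if (inherits(chi, "qsm_volume")) {
    if (is.null(geometry)) geometry <- chi$geometry
    vals <- chi$values
    mask <- chi$mask
  } else {
    if (is.null(geometry)) stop("geometry required for a bare array input")
    vals <- as.array(chi)
    mask <- NULL
  }
  stopifnot_geometry(geometry)
  if (length(dim(vals)) != 3) stop("chi must be a 3D volume")
  if (any(!is.finite(vals))) stop("chi must be finite")
  d0 <- dim(vals)
  if (pad) {
    padded <- array(0, 2 * d0)
    padded[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3])] <- vals
    vals <- padded
  }
  kern <- build_dipole_kernel(dim(vals), geometry, dc_convention)
  field <- Re(stats::fft(stats::fft(vals) * kern$values, inverse = TRUE)) /
    length(vals)
  if (pad) field <- field[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3])]
  local_field_volume(field, geometry, mask)
}

#' Naive-transform oracle for the forward field
#'
#' Computes the same quantity as [forward_field()] by explicit discrete
#' Fourier summation (per-axis DFT matrices, no fast transform), as an
#' independent cross-check.  Cost grows as O(N^4) per axis, so grids are
#' limited to 16^3.
#'
#' @inheritParams forward_field
#' @return A [local_field_volume()].
#' @export
forward_field_oracle <- function(chi, geometry = NULL, dc_convention = 0) {
  if (inherits(chi, "qsm_volume")) {
    if (is.null(geometry)) geometry <- chi$geometry
    vals <- chi$values
    mask <- chi$mask
  } else {
    if (is.null(geometry)) stop("geometry required for a bare array input")
    vals <- as.array(chi)
    mask <- NULL
  }
  stopifnot_geometry(geometry)
  d0 <- dim(vals)
  if (any(d0 > 16)) stop("oracle restricted to grids <= 16^3")
  dft <- function(n, inverse = FALSE) {
    jk <- outer(0:(n - 1), 0:(n - 1))
    sgn <- if (inverse) 2i else -2i
    exp(sgn * pi * jk / n)
  }
  apply_axis <- function(a, m, axis) {
    # multiply DFT matrix along one axis of a 3D array
    perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    res <- m %*% matrix(ap, nrow = dp[1])
    dim(res) <- dp
    aperm(res, order(perm))
  }
  spec <- vals
  for (axis in 1:3) spec <- apply_axis(spec, dft(d0[axis]), axis)
  kern <- build_dipole_kernel(d0, geometry, dc_convention)
  spec <- spec * kern$values
  for (axis in 1:3) {
    spec <- apply_axis(spec, dft(d0[axis], inverse = TRUE), axis)
  }
  local_field_volume(Re(spec) / prod(d0), geometry, mask)
}
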