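#' Acquisition geometry: voxel size and main-field orientation
#'
#' Bundles the two acquisition parameters that determine the dipole response
#' of a gradient-echo measurement: the voxel size in mm and the unit vector of
#' the main magnetic field B0 expressed in image axes.  Their concatenation is
#' the six-component side-information vector fed to the filter-manifold
#' network of the adaptive U-Net.
#'
#' @param voxel_size Numeric length-3, voxel edge lengths in mm; all > 0.
#' @param b0_direction Numeric length-3, direction of B0 in image axes; it is
#'   normalized to unit length (an axial acquisition is `c(0, 0, 1)`).
#' @return An object of class `acq_geometry` with fields `voxel_size`,
#'   `b0_direction` (unit norm) and `side_info` (their concatenation).
#' @examples
#' g <- acq_geometry(c(0.57, 0.57, 2), c(-0.03, -0.42, 0.90))
#' angle_to_axis(g$b0_direction)
#' @export
acq_geometry <- function(voxel_size = c(1, 1, 1), b0_direction = c(0, 0, 1)) {
  voxel_size <- as.numeric(voxel_size)
  b0_direction <- as.numeric(b0_direction)
  if (length(voxel_size) != 3 || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    stop("invalid geometry: voxel_size must be 3 positive finite values (mm)")
  }
  if (length(b0_direction) != 3 || any(!is.finite(b0_direction))) {
    stop("invalid geometry: b0_direction must be a finite 3-vector")
  }
  nrm <- sqrt(sum(b0_direction^2))
  if (nrm < 1e-12) {
    stop("invalid geometry: b0_direction has zero norm")
  }
  o <- b0_direction / nrm
  structure(
    list(voxel_size = voxel_size, b0_direction = o,
         side_info = c(voxel_size, o)),
    class = "acq_geometry"
  )
}

#' @export
print.acq_geometry <- function(x, ...) {
  cat(sprintf("Acquisition geometry: voxel size [%s] mm, B0 [%s] (%.1f deg from z)\n",
              paste(format(x$voxel_size, digits = 3), collapse = ", "),
              paste(format(x$b0_direction, digits = 3), collapse = ", "),
              angle_to_axis(x$b0_direction)))
  invisible(x)
}

is_acq_geometry <- function(x) inherits(x, "acq_geometry")

stopifnot_geometry <- function(geometry) {
  if (!is_acq_geometry(geometry)) {
    stop("expected an 'acq_geometry' object (see acq_geometry())")
  }
  geometry
}

#' Tilt angle of the B0 direction relative to the slice axis
#'
#' Angle in degrees between a (not necessarily normalized) orientation vector
#' and the image z-axis `c(0, 0, 1)`; 0 for an axial field of view.
#'
#' @param o Numeric length-3 orientation vector, non-zero.
#' @return Angle in degrees in \[0, 180\].
#' @examples
#' angle_to_axis(c(0, 0, 1))           # 0
#' angle_to_axis(c(-0.03, -0.42, 0.90)) # ~25 degrees
#' @export
angle_to_axis <- function(o) {
  o <- as.numeric(o)
  if (length(o) != 3 || any(!is.finite(o))) stop("o must be a finite 3-vector")
  nrm <- sqrt(sum(o^2))
  if (nrm < 1e-12) stop("o must be non-zero")
  acos(pmin(1, pmax(-1, o[3] / nrm))) * 180 / pi
}

#' Voxel aspect ratio (through-plane / in-plane)
#'
#' Ratio of the slice-encoding voxel dimension to the in-plane voxel
#' dimension.  If the two in-plane components differ, their mean is used with
#' a warning.
#'
#' @param v Numeric length-3 voxel size in mm, all components > 0.
#' @return Scalar aspect ratio.
#' @examples
#' voxel_aspect_ratio(c(0.57, 0.57, 2)) # ~3.5
#' @export
voxel_aspect_ratio <- function(v) {
  v <- as.numeric(v)
  if (length(v) != 3 || any(!is.finite(v)) || any(v <= 0)) {
    stop("v must be 3 positive voxel dimensions")
  }
  inplane <- if (isTRUE(all.equal(v[1], v[2]))) {
    v[1]
  } else {
    warning("in-plane voxel dimensions differ; using their mean")
    mean(v[1:2])
  }
  v[3] / inplane
}
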