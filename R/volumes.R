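#' Susceptibility and local-field volume containers
#'
#' Light S3 wrappers around a 3D numeric array carrying the acquisition
#' geometry and an optional binary mask.  Susceptibility values are in ppm;
#' local-field values are the relative field perturbation B/B0 in ppm at the
#' reference field strength.
#'
#' @param values 3D numeric array (finite).
#' @param geometry An [acq_geometry()].
#' @param mask Optional logical/0-1 array of the same shape.
#' @return An object of class `susceptibility_volume` or `local_field_volume`
#'   (both inherit from `qsm_volume`).
#' @export
susceptibility_volume <- function(values, geometry = acq_geometry(),
                                  mask = NULL) {
  new_qsm_volume(values, geometry, mask, "susceptibility_volume")
}

#' @rdname susceptibility_volume
#' @param reference_field_T Field strength (tesla) at which the perturbation
#'   is expressed; the synthetic pipeline works at 1 T.
#' @export
local_field_volume <- function(values, geometry = acq_geometry(), mask = NULL,
                               reference_field_T = 1) {
  v <- new_qsm_volume(values, geometry, mask, "local_field_volume")
  v$reference_field_T <- reference_field_T
  v
}

new_qsm_volume <- function(values, geometry, mask, class) {
  stopifnot_geometry(geometry)
  values <- as.array(values)
  if (length(dim(values)) != 3) stop("values must be a 3D array")
  if (any(!is.finite(values))) stop("values must be finite")
  if (!is.null(mask)) {
    mask <- as.array(mask)
    if (!identical(dim(mask), dim(values))) {
      stop("mask shape must match values shape")
    }
    mask <- array(mask != 0, dim(mask))
  }
  structure(list(values = values, geometry = geometry, mask = mask),
            class = c(class, "qsm_volume"))
}

#' @export
print.qsm_volume <- function(x, ...) {
  kind <- if (inherits(x, "susceptibility_volume")) "Susceptibility" else
    "Local field"
  cat(sprintf("%s volume %s (ppm), %s mask\n", kind,
              paste(dim(x$values), collapse = "x"),
              if (is.null(x$mask)) "no" else "with"))
  print(x$geometry)
  invisible(x)
}

#' @export
dim.qsm_volume <- function(x) dim(x$values)

as_volume_values <- function(x) {
  if (inherits(x, "qsm_volume")) x$values else as.array(x)
}
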