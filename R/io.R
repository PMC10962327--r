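#' Read a NIfTI volume with acquisition geometry
#'
#' Loads a 3D NIfTI volume and derives the acquisition geometry: voxel sizes
#' from the header zooms and the B0 direction from the direction-cosine
#' matrix under the convention that B0 lies along the scanner z-axis (the
#' third row of the rotation part of the affine, normalized).  Both can be
#' overridden; every geometry source is reported via a message so nothing is
#' defaulted silently.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param voxel_size Optional length-3 override (mm).
#' @param b0_direction Optional length-3 override.
#' @param quiet Suppress the geometry notice.
#' @return A `volume_record`: list with `values` (3D array), `geometry`
#'   ([acq_geometry()]), `affine` and `path`.
#' @export
read_volume <- function(path, voxel_size = NULL, b0_direction = NULL,
                        quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4 && d[4] == 1) d <- d[1:3]
  if (length(d) != 3) {
    stop("expected a 3D volume, got dims [", paste(dim(img), collapse = ", "),
         "]")
  }
  vals <- array(as.numeric(img), d)  # plain array, no image attributes
  affine <- unclass(RNifti::xform(img))
  rot <- affine[1:3, 1:3]
  if (abs(det(rot)) < 1e-12) stop("singular affine in ", path)
  zooms <- sqrt(colSums(rot^2))
  src_v <- "header zooms"
  src_o <- "affine direction cosines (B0 = scanner z)"
  if (!is.null(voxel_size)) {
    zooms <- as.numeric(voxel_size)
    src_v <- "user override"
  }
  if (is.null(b0_direction)) {
    rotn <- sweep(rot, 2, sqrt(colSums(rot^2)), "/")
    b0_direction <- rotn[3, ]
  } else {
    src_o <- "user override"
  }
  geometry <- acq_geometry(zooms, b0_direction)
  if (!quiet) {
    message(sprintf("geometry for %s: voxel size [%s] mm (%s); B0 [%s] (%s)",
                    basename(path),
                    paste(format(geometry$voxel_size, digits = 3), collapse = ", "),
                    src_v,
                    paste(format(geometry$b0_direction, digits = 3), collapse = ", "),
                    src_o))
  }
  structure(list(values = vals, geometry = geometry, affine = affine,
                 path = path),
            class = "volume_record")
}

#' Write a volume to NIfTI
#'
#' Writes the values at double precision so a read/write round trip is
#' bit-identical, encodes the voxel size in the header zooms, embeds the B0
#' direction in the direction-cosine matrix (third row of the rotation) and
#' records the unit (ppm) in the header description field.
#'
#' @param volume A [qsm_volume], `volume_record`, or 3D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param geometry Geometry when `volume` is a bare array.
#' @param descrip Header description string.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, geometry = NULL, descrip = "ppm") {
  if (inherits(volume, "qsm_volume") || inherits(volume, "volume_record")) {
    if (is.null(geometry)) geometry <- volume$geometry
    vals <- volume$values
  } else {
    vals <- as.array(volume)
  }
  if (is.null(geometry)) stop("geometry required")
  stopifnot_geometry(geometry)
  vals <- vals * 1.0  # masks become 0/1 doubles
  affine <- b0_affine(geometry)
  hdr <- RNifti::niftiHeader(list(
    pixdim = c(1, geometry$voxel_size, 0, 0, 0, 0),
    srow_x = affine[1, ], srow_y = affine[2, ], srow_z = affine[3, ],
    sform_code = 2L, descrip = descrip))
  img <- RNifti::asNifti(vals, reference = hdr, datatype = "double")
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

# rotation whose third row is the B0 direction (completed orthonormally),
# scaled by the voxel size: the affine of an acquisition tilted so that the
# scanner z-axis has image-axis components o
b0_affine <- function(geometry) {
  o <- geometry$b0_direction
  ref <- if (abs(o[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  r1 <- ref - sum(ref * o) * o
  r1 <- r1 / sqrt(sum(r1^2))
  r2 <- c(o[2] * r1[3] - o[3] * r1[2],
          o[3] * r1[1] - o[1] * r1[3],
          o[1] * r1[2] - o[2] * r1[1])
  rot <- rbind(r1, r2, o)
  affine <- diag(4)
  affine[1:3, 1:3] <- rot %*% diag(geometry$voxel_size)
  affine
}
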