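#' Shape-scene specification for synthetic susceptibility phantoms
#'
#' Parameters of the synthetic training scenes: random rectangles, extruded
#' polygons and ellipsoids with susceptibilities drawn from N(0, 0.25) ppm,
#' each shape blurred with its own Gaussian kernel (sd uniform on
#' \[0, 0.8\] voxels), composited by averaging where shapes overlap, plus a
#' brain-like mask formed as the complement of ellipsoids packed into the
#' image border regions.
#'
#' @param grid_shape Integer length-3 scene dimensions.
#' @param rect_count_range,ellipsoid_count_range Inclusive ranges from which
#'   the number of rectangles / ellipsoids is drawn uniformly.
#' @param polygon_count Fixed number of extruded polygons.
#' @param mask_ellipsoid_count Number of border ellipsoids whose union is
#'   removed from the mask.
#' @param chi_mean,chi_sd Gaussian parameters of per-shape susceptibility (ppm).
#' @param blur_sd_range Uniform range of the per-shape blur sd (voxels).
#' @param border_frac Width of the border band holding mask ellipsoids, as a
#'   fraction of each dimension.
#' @param box_extent,ellipsoid_extent,polygon_radius,polygon_thickness,mask_ellipsoid_extent
#'   Uniform ranges of the shape extents as fractions of the grid dimension
#'   (box side lengths, ellipsoid semi-axes, polygon vertex radii, extruded
#'   slab thickness, border-ellipsoid semi-axes).  At reduced grid sizes
#'   these should be enlarged so the scene statistics (coverage, value
#'   spread) stay comparable to the full-size recipe.
#' @return A `shape_scene_spec` list.
#' @export
shape_scene_spec <- function(grid_shape = c(320, 320, 320),
                             rect_count_range = c(80, 150),
                             ellipsoid_count_range = c(200, 300),
                             polygon_count = 50,
                             mask_ellipsoid_count = 300,
                             chi_mean = 0, chi_sd = 0.25,
                             blur_sd_range = c(0, 0.8),
                             border_frac = 0.15,
                             box_extent = c(0.02, 0.20),
                             ellipsoid_extent = c(0.01, 0.12),
                             polygon_radius = c(0.02, 0.15),
                             polygon_thickness = c(0.02, 0.15),
                             mask_ellipsoid_extent = c(0.05, 0.15)) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 4),
            all(rect_count_range >= 0), all(ellipsoid_count_range >= 0),
            polygon_count >= 0, mask_ellipsoid_count >= 0,
            chi_sd >= 0, all(blur_sd_range >= 0),
            diff(rect_count_range) >= 0, diff(ellipsoid_count_range) >= 0,
            border_frac >= 0, border_frac <= 0.5,
            all(box_extent > 0), all(ellipsoid_extent > 0),
            all(polygon_radius > 0), all(polygon_thickness > 0),
            all(mask_ellipsoid_extent > 0))
  structure(list(grid_shape = grid_shape,
                 rect_count_range = rect_count_range,
                 ellipsoid_count_range = ellipsoid_count_range,
                 polygon_count = polygon_count,
                 mask_ellipsoid_count = mask_ellipsoid_count,
                 chi_mean = chi_mean, chi_sd = chi_sd,
                 blur_sd_range = blur_sd_range, border_frac = border_frac,
                 box_extent = box_extent,
                 ellipsoid_extent = ellipsoid_extent,
                 polygon_radius = polygon_radius,
                 polygon_thickness = polygon_thickness,
                 mask_ellipsoid_extent = mask_ellipsoid_extent),
            class = "shape_scene_spec")
}

# run code under a seed without disturbing the caller's RNG state
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# internal rasterizers return a bounding sub-box: list(lo, hi) in 1-based
# voxel indices plus the logical sub-array `ind`, or NULL when empty; the
# exported rasterize_* functions embed them into full-grid arrays
embed_sub <- function(sub, grid) {
  out <- array(FALSE, grid)
  if (is.null(sub)) return(out)
  out[sub$lo[1]:sub$hi[1], sub$lo[2]:sub$hi[2], sub$lo[3]:sub$hi[3]] <- sub$ind
  out
}

raster_box_sub <- function(corner_lo, corner_hi, grid) {
  if (any(corner_hi < corner_lo)) stop("inverted corners: lo must be <= hi")
  if (any(corner_lo < 0) || any(corner_hi > grid)) {
    stop("corners must lie inside the grid")
  }
  if (any(corner_hi <= corner_lo)) return(NULL)
  lo <- pmax(1L, as.integer(ceiling(corner_lo)) + 1L)
  hi <- pmin(grid, as.integer(ceiling(corner_hi)))
  if (any(hi < lo)) return(NULL)
  list(lo = lo, hi = hi, ind = array(TRUE, hi - lo + 1L))
}

raster_ellipsoid_sub <- function(center, semi_axes, grid) {
  if (any(semi_axes <= 0)) stop("semi-axes must be positive")
  lo <- pmax(0L, as.integer(floor(center - semi_axes)))
  hi <- pmin(grid - 1L, as.integer(ceiling(center + semi_axes)))
  if (any(hi < lo)) return(NULL)
  ax <- lapply(1:3, function(a) seq.int(lo[a], hi[a]))
  q1 <- ((ax[[1]] - center[1]) / semi_axes[1])^2
  q2 <- ((ax[[2]] - center[2]) / semi_axes[2])^2
  q3 <- ((ax[[3]] - center[3]) / semi_axes[3])^2
  ind <- outer(outer(q1, q2, `+`), q3, `+`) <= 1
  if (!any(ind)) return(NULL)
  list(lo = lo + 1L, hi = hi + 1L, ind = ind)
}

raster_polygon_sub <- function(vertices_2d, extrusion_range, grid) {
  v <- as.matrix(vertices_2d)
  if (nrow(v) < 3 || ncol(v) != 2) stop("need >= 3 planar vertices")
  n <- nrow(v)
  area2 <- sum(v[, 1] * (v[c(2:n, 1), 2] - v[c(n, 1:(n - 1)), 2]))
  if (abs(area2) < 1e-12) stop("degenerate (collinear) polygon")
  zlo <- max(ceiling(extrusion_range[1]), 0)
  zhi <- min(ceiling(extrusion_range[2]) - 1, grid[3] - 1L)
  if (zhi < zlo) return(NULL)
  xlo <- max(0L, floor(min(v[, 1]))); xhi <- min(grid[1] - 1L, ceiling(max(v[, 1])))
  ylo <- max(0L, floor(min(v[, 2]))); yhi <- min(grid[2] - 1L, ceiling(max(v[, 2])))
  if (xhi < xlo || yhi < ylo) return(NULL)
  px <- rep(xlo:xhi, yhi - ylo + 1L)
  py <- rep(ylo:yhi, each = xhi - xlo + 1L)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  if (!any(inside)) return(NULL)
  slab <- array(inside, c(xhi - xlo + 1L, yhi - ylo + 1L))
  nz <- zhi - zlo + 1L
  list(lo = as.integer(c(xlo, ylo, zlo)) + 1L,
       hi = as.integer(c(xhi, yhi, zhi)) + 1L,
       ind = array(rep(slab, nz), c(dim(slab), nz)))
}

#' Rasterize an axis-aligned box
#'
#' Voxel coordinates are 0-based indices; the box is half-open, covering
#' voxels with index `lo <= i < hi` per axis.
#'
#' @param corner_lo,corner_hi Numeric length-3 corners, `lo <= hi`, inside
#'   the grid.
#' @param grid Integer length-3 grid dimensions.
#' @return Logical 3D array.
#' @export
rasterize_box <- function(corner_lo, corner_hi, grid) {
  grid <- as.integer(grid)
  embed_sub(raster_box_sub(corner_lo, corner_hi, grid), grid)
}

#' Rasterize an ellipsoid
#'
#' Inclusion test of 0-based voxel centres against
#' `sum(((i - center)/semi_axes)^2) <= 1`.
#'
#' @param center Numeric length-3 centre in voxel coordinates.
#' @param semi_axes Numeric length-3 positive semi-axes in voxels.
#' @param grid Integer length-3 grid dimensions.
#' @return Logical 3D array.
#' @export
rasterize_ellipsoid <- function(center, semi_axes, grid) {
  grid <- as.integer(grid)
  embed_sub(raster_ellipsoid_sub(center, semi_axes, grid), grid)
}

#' Rasterize an extruded 2D polygon
#'
#' An even-odd point-in-polygon test of the 0-based (x, y) voxel centres,
#' replicated across the half-open z slab `extrusion_range[1] <= z <
#' extrusion_range[2]`.
#'
#' @param vertices_2d Numeric matrix (n >= 3 rows, 2 columns) of polygon
#'   vertices in voxel coordinates.
#' @param extrusion_range Numeric length-2 half-open z-range.
#' @param grid Integer length-3 grid dimensions.
#' @return Logical 3D array.
#' @export
rasterize_polygon <- function(vertices_2d, extrusion_range, grid) {
  grid <- as.integer(grid)
  embed_sub(raster_polygon_sub(vertices_2d, extrusion_range, grid), grid)
}

# accumulate one valued, individually blurred shape (bounding sub-box form)
# into the running sums
accumulate_shape <- function(acc, sub, value, blur_sd) {
  if (is.null(sub)) return(acc)
  g <- dim(acc$val)
  margin <- as.integer(ceiling(4 * blur_sd))
  lo <- pmax(1L, sub$lo - margin)
  hi <- pmin(g, sub$hi + margin)
  vals <- array(0, hi - lo + 1L)
  off <- sub$lo - lo
  d <- dim(sub$ind)
  vals[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]),
       off[3] + seq_len(d[3])] <- sub$ind * 1.0
  if (blur_sd > 0) {
    vals <- gaussian_blur3d_cpp(vals, rep(blur_sd, 3), 0L)
  }
  cur_v <- acc$val[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  cur_w <- acc$wt[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  acc$val[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
    as.numeric(cur_v) + value * as.numeric(vals)
  acc$wt[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
    as.numeric(cur_w) + as.numeric(vals)
  acc
}

#' Sample a synthetic susceptibility scene
#'
#' Draws the shape counts, places rectangles, ellipsoids and extruded
#' polygons uniformly over the grid, assigns each a susceptibility from
#' N(`chi_mean`, `chi_sd`) ppm, blurs each shape individually (sd uniform on
#' `blur_sd_range`) and composites by averaging overlapping contributions.
#' The brain-like mask is the complement of `mask_ellipsoid_count` ellipsoids
#' placed in the image border band.  The result is a pure function of
#' `(spec, seed)`.
#'
#' @param spec A [shape_scene_spec()].
#' @param seed Integer seed making the scene reproducible.
#' @param geometry Geometry attached to the returned volume.
#' @return A [susceptibility_volume()] with mask.
#' @export
sample_scene <- function(spec = shape_scene_spec(), seed = 1,
                         geometry = acq_geometry()) {
  stopifnot(inherits(spec, "shape_scene_spec"))
  g <- spec$grid_shape
  with_local_seed(seed, {
    n_rect <- sample_count(spec$rect_count_range)
    n_ell <- sample_count(spec$ellipsoid_count_range)
    n_poly <- spec$polygon_count
    acc <- list(val = array(0, g), wt = array(0, g))
    for (i in seq_len(n_rect)) {
      size <- runif(3, spec$box_extent[1], spec$box_extent[2]) * g
      lo <- runif(3, 0, g - size)
      acc <- accumulate_shape(acc, raster_box_sub(lo, lo + size, g),
                              rnorm(1, spec$chi_mean, spec$chi_sd),
                              runif(1, spec$blur_sd_range[1], spec$blur_sd_range[2]))
    }
    for (i in seq_len(n_ell)) {
      semi <- pmax(1, runif(3, spec$ellipsoid_extent[1], spec$ellipsoid_extent[2]) * g)
      ctr <- runif(3, 0, g - 1)
      acc <- accumulate_shape(acc, raster_ellipsoid_sub(ctr, semi, g),
                              rnorm(1, spec$chi_mean, spec$chi_sd),
                              runif(1, spec$blur_sd_range[1], spec$blur_sd_range[2]))
    }
    for (i in seq_len(n_poly)) {
      nv <- sample(3:8, 1)
      ctr <- runif(2, 0, g[1:2] - 1)
      ang <- sort(runif(nv, 0, 2 * pi))
      rad <- runif(nv, spec$polygon_radius[1], spec$polygon_radius[2]) * mean(g[1:2])
      verts <- cbind(ctr[1] + rad * cos(ang), ctr[2] + rad * sin(ang))
      thick <- runif(1, spec$polygon_thickness[1], spec$polygon_thickness[2]) * g[3]
      z0 <- runif(1, 0, g[3] - thick)
      acc <- accumulate_shape(acc, raster_polygon_sub(verts, c(z0, z0 + thick), g),
                              rnorm(1, spec$chi_mean, spec$chi_sd),
                              runif(1, spec$blur_sd_range[1], spec$blur_sd_range[2]))
    }
    vals <- acc$val / pmax(acc$wt, 1)
    mask <- array(TRUE, g)
    for (i in seq_len(spec$mask_ellipsoid_count)) {
      semi <- pmax(1, runif(3, spec$mask_ellipsoid_extent[1], spec$mask_ellipsoid_extent[2]) * g)
      ctr <- sample_border_point(g, spec$border_frac)
      sub <- raster_ellipsoid_sub(ctr, semi, g)
      if (!is.null(sub)) {
        cur <- mask[sub$lo[1]:sub$hi[1], sub$lo[2]:sub$hi[2],
                    sub$lo[3]:sub$hi[3], drop = FALSE]
        mask[sub$lo[1]:sub$hi[1], sub$lo[2]:sub$hi[2],
             sub$lo[3]:sub$hi[3]] <- as.logical(cur) & !as.logical(sub$ind)
      }
    }
    susceptibility_volume(vals, geometry, mask)
  })
}

sample_count <- function(range) {
  if (range[2] <= range[1]) return(as.integer(range[1]))
  sample(seq.int(range[1], range[2]), 1)
}

# uniform point within the border band (any coordinate within border_frac of
# an edge); sampled by picking a face-adjacent band for one random axis
sample_border_point <- function(g, frac) {
  ctr <- runif(3, 0, g - 1)
  axis <- sample(1:3, 1)
  band <- frac * (g[axis] - 1)
  ctr[axis] <- if (runif(1) < 0.5) runif(1, 0, band) else
    runif(1, g[axis] - 1 - band, g[axis] - 1)
  ctr
}

#' Acquisition-geometry sampler specification
#'
#' Emulates the training-time augmentation of acquisition parameters: with
#' probability `1 - p_var` the standard geometry (1 mm isotropic, axial B0)
#' is returned, otherwise per-axis voxel sizes are drawn from a truncated
#' N(1, 1.5) mm and the axial field vector (0, 0, 1) is perturbed by
#' additive Gaussian noise on its components and re-normalized.
#'
#' @param voxel_mean,voxel_sd Gaussian parameters of the voxel size (mm).
#' @param voxel_bounds Rejection bounds keeping voxel sizes positive (mm).
#' @param xy_sd,z_sd Perturbation sd of the x/y and z orientation components.
#' @param p_var Probability of varying the geometry at all.
#' @return A `geometry_sampler_spec` list.
#' @export
geometry_sampler_spec <- function(voxel_mean = 1, voxel_sd = 1.5,
                                  voxel_bounds = c(0.5, 3.5),
                                  xy_sd = 1 / 11, z_sd = 1 / 5,
                                  p_var = 0.8) {
  stopifnot(p_var >= 0, p_var <= 1, voxel_bounds[1] > 0,
            voxel_bounds[2] > voxel_bounds[1], voxel_sd >= 0,
            xy_sd >= 0, z_sd >= 0)
  structure(list(voxel_mean = voxel_mean, voxel_sd = voxel_sd,
                 voxel_bounds = voxel_bounds, xy_sd = xy_sd, z_sd = z_sd,
                 p_var = p_var),
            class = "geometry_sampler_spec")
}

#' Sample an acquisition geometry
#'
#' @param spec A [geometry_sampler_spec()].
#' @param seed Integer seed.
#' @return An [acq_geometry()].
#' @export
sample_geometry <- function(spec = geometry_sampler_spec(), seed = 1) {
  stopifnot(inherits(spec, "geometry_sampler_spec"))
  with_local_seed(seed, {
    if (runif(1) >= spec$p_var) {
      acq_geometry(c(1, 1, 1), c(0, 0, 1))
    } else {
      v <- vapply(1:3, function(i) {
        repeat {
          x <- rnorm(1, spec$voxel_mean, spec$voxel_sd)
          if (x >= spec$voxel_bounds[1] && x <= spec$voxel_bounds[2]) return(x)
        }
      }, numeric(1))
      o <- c(0, 0, 1) + c(rnorm(2, 0, spec$xy_sd), rnorm(1, 0, spec$z_sd))
      acq_geometry(v, o)
    }
  })
}

#' Augment a volume patch
#'
#' Applies the training-time patch augmentations: multiplicative scaling of
#' the susceptibilities, additive Gaussian noise, random axis flips and
#' random 90-degree rotations (exact voxel permutations).  Pass `params` to
#' replay a specific augmentation (e.g. on the paired field patch).
#'
#' @param patch 3D numeric array (cubic for rotations to apply).
#' @param options List of toggles/parameters: `scale_range` (default
#'   `c(0.5, 2)`), `noise_sd` (ppm, default 0.01), `flip`, `rotate`,
#'   `scale`, `noise` logical toggles.
#' @param params Augmentation parameters to replay (as returned in
#'   `$params`); when `NULL` they are drawn from the current RNG.
#' @param seed Optional seed for reproducible draws.
#' @return List with `values` (augmented patch) and `params`.
#' @export
augment_patch <- function(patch, options = list(), params = NULL, seed = NULL) {
  opt <- utils::modifyList(list(scale = TRUE, noise = TRUE, flip = TRUE,
                                rotate = TRUE, scale_range = c(0.5, 2),
                                noise_sd = 0.01), options)
  run <- function() {
    if (is.null(params)) {
      params <- list(
        scale = if (opt$scale) runif(1, opt$scale_range[1], opt$scale_range[2]) else 1,
        flips = if (opt$flip) runif(3) < 0.5 else c(FALSE, FALSE, FALSE),
        rot_axis = if (opt$rotate) sample(1:3, 1) else 1L,
        rot_k = if (opt$rotate) sample(0:3, 1) else 0L,
        noise_seed = sample.int(.Machine$integer.max, 1))
    }
    v <- patch * params$scale
    for (a in 1:3) if (params$flips[a]) v <- flip_axis(v, a)
    v <- rot90_3d(v, params$rot_axis, params$rot_k)
    if (opt$noise && opt$noise_sd > 0) {
      v <- v + with_local_seed(params$noise_seed,
                               array(rnorm(length(v), 0, opt$noise_sd), dim(v)))
    }
    list(values = v, params = params)
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}

flip_axis <- function(a, axis) {
  d <- dim(a)
  idx <- rep(list(quote(expr = )), 3)
  idx[[axis]] <- d[axis]:1
  do.call(`[`, c(list(a), idx))
}

#' Transform an acquisition geometry consistently with a patch augmentation
#'
#' Axis flips and 90-degree rotations of a susceptibility/field pair keep
#' the dipole relation valid only if the B0 direction (and, for rotations,
#' the voxel-size components) are transformed with the voxel grid.  Given
#' the parameters drawn by [augment_patch()], this returns the geometry the
#' augmented pair actually obeys.
#'
#' @param geometry An [acq_geometry()].
#' @param params Augmentation parameters (`$params` of [augment_patch()]).
#' @return The transformed [acq_geometry()].
#' @export
augment_geometry <- function(geometry, params) {
  stopifnot_geometry(geometry)
  o <- geometry$b0_direction
  v <- geometry$voxel_size
  for (a in 1:3) if (params$flips[a]) o[a] <- -o[a]
  k <- params$rot_k %% 4
  if (k > 0) {
    plane <- setdiff(1:3, params$rot_axis)
    for (i in seq_len(k)) {
      # matches rot90_3d: swap the plane axes, then flip the first
      o[plane] <- o[rev(plane)]
      v[plane] <- v[rev(plane)]
      o[plane[1]] <- -o[plane[1]]
    }
  }
  acq_geometry(v, o)
}

# 90-degree rotation about one axis, k quarter turns
rot90_3d <- function(a, axis, k) {
  k <- k %% 4
  if (k == 0) return(a)
  plane <- setdiff(1:3, axis)
  for (i in seq_len(k)) {
    perm <- 1:3
    perm[plane] <- plane[2:1]
    a <- flip_axis(aperm(a, perm), plane[1])
  }
  a
}

#' Build one paired training example
#'
#' Simulates the local field from a susceptibility scene under the given
#' acquisition geometry (fast k-space forward convolution) and bundles it
#' with the side-information vector.
#'
#' @param scene A [susceptibility_volume()].
#' @param geometry An [acq_geometry()]; defaults to the scene's.
#' @return List with `field` ([local_field_volume()]), `chi` (the scene under
#'   `geometry`) and `side_info` (numeric length-6).
#' @export
make_training_example <- function(scene, geometry = scene$geometry) {
  stopifnot_geometry(geometry)
  chi <- susceptibility_volume(scene$values, geometry, scene$mask)
  field <- forward_field(chi)
  list(field = field, chi = chi, side_info = geometry$side_info)
}

#' Lesion specification and insertion
#'
#' Assigns fixed susceptibility values to labelled mask regions, smooths the
#' inserted component with a Gaussian kernel and adds it to the base volume,
#' emulating simulated pathology on top of a normal susceptibility map.
#'
#' @param label_mask Integer 3D array; 0 = background, labels index `values`.
#' @param values Named or plain numeric vector of per-label susceptibilities
#'   (ppm); the defaults are -1.0, -0.5, 0.5 and 1.0 for labels 1..4.
#' @param smoothing_sd Gaussian smoothing sd in voxels.
#' @return A `lesion_spec` list.
#' @export
lesion_spec <- function(label_mask, values = c(-1.0, -0.5, 0.5, 1.0),
                        smoothing_sd = 0.5) {
  label_mask <- as.array(label_mask)
  stopifnot(smoothing_sd >= 0)
  labs <- setdiff(sort(unique(as.integer(label_mask))), 0L)
  if (length(labs) && any(labs > length(values) | labs < 1)) {
    stop("label mask references labels without susceptibility values")
  }
  structure(list(label_mask = label_mask, values = values,
                 smoothing_sd = smoothing_sd),
            class = "lesion_spec")
}

#' @rdname lesion_spec
#' @param chi A [susceptibility_volume()].
#' @param spec A [lesion_spec()].
#' @return `insert_lesions` returns the modified [susceptibility_volume()].
#' @export
insert_lesions <- function(chi, spec) {
  stopifnot(inherits(spec, "lesion_spec"))
  if (!identical(dim(chi$values), dim(spec$label_mask))) {
    stop("lesion mask shape must match the volume")
  }
  delta <- array(0, dim(chi$values))
  labs <- setdiff(sort(unique(as.integer(spec$label_mask))), 0L)
  for (l in labs) delta[spec$label_mask == l] <- spec$values[l]
  if (spec$smoothing_sd > 0 && length(labs)) {
    delta <- gaussian_blur3d_cpp(delta, rep(spec$smoothing_sd, 3), 0L)
  }
  susceptibility_volume(chi$values + delta, chi$geometry, chi$mask)
}

#' Trilinear resampling to a new voxel size
#'
#' Interpolates a volume onto a grid with the requested voxel size, keeping
#' the physical field of view (voxel-centre coordinate mapping); used to
#' augment isotropic data to anisotropic voxel sizes.
#'
#' @param volume A [qsm_volume] (susceptibility or local field).
#' @param new_voxel_size Numeric length-3 target voxel size in mm.
#' @return A volume of the same class on the new grid, with updated geometry;
#'   a mask is resampled and re-thresholded at 0.5.
#' @export
resample_trilinear <- function(volume, new_voxel_size) {
  stopifnot(inherits(volume, "qsm_volume"))
  new_voxel_size <- as.numeric(new_voxel_size)
  if (any(new_voxel_size <= 0)) stop("target voxel size must be positive")
  old_v <- volume$geometry$voxel_size
  d0 <- dim(volume$values)
  d1 <- as.integer(pmax(1, round(d0 * old_v / new_voxel_size)))
  if (prod(d1) == 0) stop("target grid is empty")
  vals <- resample_trilinear_cpp(volume$values, d1, old_v, new_voxel_size)
  geo <- acq_geometry(new_voxel_size, volume$geometry$b0_direction)
  mask <- NULL
  if (!is.null(volume$mask)) {
    mask <- resample_trilinear_cpp(volume$mask * 1.0, d1, old_v,
                                   new_voxel_size) >= 0.5
  }
  if (inherits(volume, "susceptibility_volume")) {
    susceptibility_volume(vals, geo, mask)
  } else {
    local_field_volume(vals, geo, mask, volume$reference_field_T)
  }
}
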