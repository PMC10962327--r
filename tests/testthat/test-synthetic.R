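test_that("box rasterization covers half-open voxel boxes", {
  g <- c(8, 8, 8)
  expect_equal(sum(rasterize_box(c(0, 0, 0), c(2, 3, 4), g)), 24)
  expect_equal(sum(rasterize_box(c(1, 1, 1), c(1, 1, 1), g)), 0)
  expect_equal(sum(rasterize_box(c(0, 0, 0), c(8, 8, 8), g)), 512)
  expect_error(rasterize_box(c(2, 2, 2), c(1, 3, 3), g), "inverted")
  expect_error(rasterize_box(c(0, 0, 0), c(9, 2, 2), g), "inside")
})

test_that("ellipsoid rasterization equals brute-force voxel-centre tests", {
  g <- c(16, 16, 16)
  one <- rasterize_ellipsoid(c(5, 5, 5), c(0.5, 0.5, 0.5), g)
  expect_equal(sum(one), 1)
  expect_true(one[6, 6, 6])
  ell <- rasterize_ellipsoid(c(7.3, 8.1, 6.9), c(3, 4, 5), g)
  co <- as.matrix(expand.grid(x = 0:15, y = 0:15, z = 0:15))
  inside <- ((co[, 1] - 7.3) / 3)^2 + ((co[, 2] - 8.1) / 4)^2 +
    ((co[, 3] - 6.9) / 5)^2 <= 1
  expect_equal(sum(ell), sum(inside))
  expect_equal(sum(rasterize_ellipsoid(c(40, 40, 40), c(2, 2, 2), g)), 0)
  expect_error(rasterize_ellipsoid(c(5, 5, 5), c(0, 1, 1), g), "positive")
})

test_that("polygon rasterization matches brute force and box consistency", {
  g <- c(20, 20, 8)
  tri <- rbind(c(2, 2), c(12, 2), c(2, 12))
  vol <- rasterize_polygon(tri, c(1, 4), g)
  co <- as.matrix(expand.grid(x = 0:19, y = 0:19))
  # brute-force even-odd test per voxel centre
  pip <- apply(co, 1, function(p) {
    n <- nrow(tri); j <- n; inside <- FALSE
    for (i in 1:n) {
      if ((tri[i, 2] > p[2]) != (tri[j, 2] > p[2]) &&
          p[1] < (tri[j, 1] - tri[i, 1]) * (p[2] - tri[i, 2]) /
            (tri[j, 2] - tri[i, 2]) + tri[i, 1]) inside <- !inside
      j <- i
    }
    inside
  })
  expect_equal(sum(vol), 3 * sum(pip))
  # square polygon reproduces the half-open box with matching footprint
  sq <- rbind(c(3, 3), c(9, 3), c(9, 11), c(3, 11))
  expect_equal(rasterize_polygon(sq, c(2, 5), g),
               rasterize_box(c(3, 3, 2), c(9, 11, 5), g))
  expect_equal(sum(rasterize_polygon(tri, c(3, 3), g)), 0)
  expect_error(rasterize_polygon(rbind(c(0, 0), c(1, 1), c(2, 2)), c(0, 2), g),
               "degenerate")
})

test_that("scene sampling is deterministic and honors the count plan", {
  spec <- shape_scene_spec(grid_shape = c(24, 24, 24),
                           rect_count_range = c(2, 5),
                           ellipsoid_count_range = c(4, 8),
                           polygon_count = 2, mask_ellipsoid_count = 20)
  s1 <- sample_scene(spec, seed = 11)
  s2 <- sample_scene(spec, seed = 11)
  expect_identical(s1$values, s2$values)
  expect_identical(s1$mask, s2$mask)
  expect_false(identical(s1$values, sample_scene(spec, seed = 12)$values))
  expect_equal(dim(s1$mask), dim(s1$values))
  # empty spec: all-zero scene, full mask
  empty <- shape_scene_spec(grid_shape = c(16, 16, 16),
                            rect_count_range = c(0, 0),
                            ellipsoid_count_range = c(0, 0),
                            polygon_count = 0, mask_ellipsoid_count = 0)
  se <- sample_scene(empty, seed = 1)
  expect_equal(max(abs(se$values)), 0)
  expect_true(all(se$mask))
})

test_that("scene susceptibilities follow the configured shape distribution", {
  # per-shape susceptibility draws are N(0, 0.25) ppm; with a handful of
  # well-separated unblurred shapes the plateau values expose the draws
  spec <- shape_scene_spec(grid_shape = c(40, 40, 40),
                           rect_count_range = c(6, 6),
                           ellipsoid_count_range = c(0, 0),
                           polygon_count = 0, mask_ellipsoid_count = 0,
                           blur_sd_range = c(0, 0))
  vals <- unlist(lapply(1:40, function(s) {
    sc <- sample_scene(spec, seed = s)
    v <- unique(round(sc$values[sc$values != 0], 10))
    v[seq_len(min(length(v), 6))]
  }))
  expect_gt(length(vals), 100)
  expect_lt(abs(mean(vals)), 3 * 0.25 / sqrt(length(vals)))
  expect_lt(abs(sd(vals) - 0.25), 0.06)
})

test_that("geometry sampler honors the variation probability and bounds", {
  expect_equal(sample_geometry(geometry_sampler_spec(p_var = 0), seed = 5),
               acq_geometry(c(1, 1, 1), c(0, 0, 1)))
  spec <- geometry_sampler_spec(p_var = 1)
  n_std <- 0
  for (s in 1:200) {
    g <- sample_geometry(spec, seed = s)
    expect_equal(sum(g$b0_direction^2), 1, tolerance = 1e-12)
    expect_true(all(g$voxel_size >= 0.5 & g$voxel_size <= 3.5))
  }
  expect_identical(sample_geometry(spec, seed = 3),
                   sample_geometry(spec, seed = 3))
  # default variation probability leaves ~20% standard geometries
  std <- sapply(1:300, function(s) {
    g <- sample_geometry(geometry_sampler_spec(), seed = s)
    identical(g$voxel_size, c(1, 1, 1))
  })
  expect_gt(mean(std), 0.10)
  expect_lt(mean(std), 0.35)
})

test_that("patch augmentations are exact voxel permutations", {
  set.seed(4)
  p <- array(rnorm(6^3), c(6, 6, 6))
  flip2 <- augment_patch(p, options = list(scale = FALSE, noise = FALSE,
                                           rotate = FALSE),
                         params = list(scale = 1, flips = c(FALSE, TRUE, FALSE),
                                       rot_axis = 1, rot_k = 0, noise_seed = 1))
  flip2b <- augment_patch(flip2$values, params = flip2$params,
                          options = list(scale = FALSE, noise = FALSE,
                                         rotate = FALSE))
  expect_equal(flip2b$values, p)
  r <- p
  prm <- list(scale = 1, flips = c(FALSE, FALSE, FALSE), rot_axis = 3,
              rot_k = 1, noise_seed = 1)
  for (i in 1:4) r <- augment_patch(r, params = prm,
                                    options = list(scale = FALSE,
                                                   noise = FALSE))$values
  expect_equal(r, p)
  sc <- augment_patch(p, params = list(scale = 2.5, flips = rep(FALSE, 3),
                                       rot_axis = 1, rot_k = 0, noise_seed = 1),
                      options = list(noise = FALSE))
  expect_equal(sc$values, 2.5 * p)
  # rotations preserve multiset of values
  rot <- augment_patch(p, params = prm, options = list(scale = FALSE,
                                                       noise = FALSE))
  expect_equal(sort(as.numeric(rot$values)), sort(as.numeric(p)))
})

test_that("training examples pair field and susceptibility consistently", {
  spec <- shape_scene_spec(grid_shape = c(16, 16, 16),
                           rect_count_range = c(2, 3),
                           ellipsoid_count_range = c(2, 4),
                           polygon_count = 1, mask_ellipsoid_count = 10)
  sc <- sample_scene(spec, seed = 2)
  g <- acq_geometry(c(1, 1, 2), c(0.1, 0, 0.99))
  ex <- make_training_example(sc, g)
  expect_equal(ex$side_info, g$side_info)
  expect_equal(dim(ex$field$values), dim(sc$values))
  expect_equal(ex$field$values,
               forward_field(sc$values, geometry = g)$values)
  # zero scene -> zero field; doubling chi doubles the field
  zero <- susceptibility_volume(array(0, c(8, 8, 8)))
  expect_equal(max(abs(make_training_example(zero)$field$values)), 0)
  sc2 <- susceptibility_volume(2 * sc$values, g)
  expect_equal(make_training_example(sc2)$field$values, 2 * ex$field$values)
})

test_that("lesion insertion assigns, smooths and adds the labelled values", {
  base <- susceptibility_volume(array(0, c(20, 20, 20)))
  lm <- array(0L, c(20, 20, 20))
  lm[3:8, 3:8, 3:8] <- 1L
  lm[12:18, 12:18, 12:18] <- 4L
  spec <- lesion_spec(lm)
  expect_equal(spec$values, c(-1.0, -0.5, 0.5, 1.0))
  out <- insert_lesions(base, spec)
  # interior voxels reach the assigned value despite smoothing
  expect_equal(out$values[5, 5, 5], -1.0, tolerance = 0.02)
  expect_equal(out$values[15, 15, 15], 1.0, tolerance = 0.02)
  # unsmoothed insertion is exact inside the label
  hard <- insert_lesions(base, lesion_spec(lm, smoothing_sd = 0))
  expect_equal(hard$values[5, 5, 5], -1.0)
  expect_equal(hard$values[15, 15, 15], 1.0)
  # empty mask leaves the volume untouched
  none <- insert_lesions(base, lesion_spec(array(0L, c(20, 20, 20))))
  expect_equal(none$values, base$values)
  expect_error(lesion_spec(array(7L, c(2, 2, 2))), "without susceptibility")
})

test_that("trilinear resampling reproduces closed-form ramps", {
  g <- acq_geometry()
  v <- susceptibility_volume(array(0.7, c(8, 8, 8)), g)
  same <- resample_trilinear(v, c(1, 1, 1))
  expect_equal(same$values, v$values)
  const <- resample_trilinear(v, c(1.7, 0.8, 1.3))
  expect_equal(max(abs(const$values - 0.7)), 0)
  # linear ramp along z: values at new voxel centres follow the ramp
  ramp <- array(rep(0:15, each = 1), c(1, 1, 16))
  ramp <- susceptibility_volume(array(rep(0:15, each = 16), c(4, 4, 16)), g)
  half <- resample_trilinear(ramp, c(1, 1, 2))
  # new centre at (k + 0.5)*2 mm sits at old index (k+0.5)*2 - 0.5
  expected <- (seq_len(8) - 0.5) * 2 - 0.5
  expect_equal(half$values[2, 2, ], expected, tolerance = 1e-12)
  expect_equal(half$geometry$voxel_size, c(1, 1, 2))
  expect_error(resample_trilinear(v, c(0, 1, 1)), "positive")
})
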