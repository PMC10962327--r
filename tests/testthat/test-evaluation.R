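ref_pair <- function(n = 12, seed = 1) {
  set.seed(seed)
  gt <- array(rnorm(n^3, sd = 0.1), c(n, n, n))
  mask <- array(runif(n^3) > 0.25, c(n, n, n))
  list(gt = gt, mask = mask)
}

test_that("NRMSE identities and scale covariance hold", {
  p <- ref_pair()
  expect_equal(nrmse(p$gt, p$gt, p$mask), 0)
  expect_equal(nrmse(2 * p$gt, p$gt, p$mask), 100)
  expect_equal(nrmse(array(0, dim(p$gt)), p$gt, p$mask), 100)
  rec <- p$gt + array(rnorm(length(p$gt), sd = 0.02), dim(p$gt))
  expect_equal(nrmse(3 * rec, 3 * p$gt, p$mask), nrmse(rec, p$gt, p$mask))
  expect_equal(nrmse(-2 * rec, -2 * p$gt, p$mask), nrmse(rec, p$gt, p$mask))
  expect_error(nrmse(p$gt, array(0, dim(p$gt))), "zero")
  expect_error(nrmse(p$gt, p$gt[1:4, 1:4, 1:4]), "shape")
})

test_that("SSIM is 1 at equality and penalized by offsets and inversion", {
  p <- ref_pair()
  expect_equal(ssim3d(p$gt, p$gt, p$mask), 1)
  off <- ssim3d(p$gt + 10 * diff(range(p$gt)), p$gt, p$mask)
  expect_lt(off, 1)
  # sign inversion: the covariance (structure) factor is negative wherever
  # the local signal dominates the stabilizer, so SSIM drops below 1 (for
  # zero-mean inputs the luminance factor is negative too, which can make
  # the product positive again -- standard SSIM behavior)
  gr <- expand.grid(x = 1:12, y = 1:12, z = 1:12)
  wiggle <- array(0.1 * sin(3 * gr$x) * cos(3 * gr$y) * sin(3 * gr$z),
                  c(12, 12, 12))
  inv <- ssim3d(0.5 - wiggle, 0.5 + wiggle)  # matched luminance, inverted
  expect_lt(inv, 0)
  expect_lt(ssim3d(-p$gt, p$gt, p$mask), 1)
  noisy <- ssim3d(p$gt + array(rnorm(length(p$gt), sd = 0.1), dim(p$gt)),
                  p$gt, p$mask)
  expect_lt(noisy, 1)
  expect_gt(noisy, -1)
  expect_error(ssim3d(p$gt, p$gt, window_halfwidth = 10), "window")
})

test_that("PSNR matches its closed forms and caps at equality", {
  p <- ref_pair()
  rng <- max(p$gt[p$mask]) - min(p$gt[p$mask])
  # MSE equal to range^2 gives 0 dB
  rec <- p$gt + rng
  expect_equal(psnr(rec, p$gt, p$mask, data_range = rng), 0)
  # halving the RMSE adds 20 log10(2) dB
  e <- array(rnorm(length(p$gt), sd = 0.05), dim(p$gt))
  d1 <- psnr(p$gt + e, p$gt, p$mask, data_range = rng)
  d2 <- psnr(p$gt + e / 2, p$gt, p$mask, data_range = rng)
  expect_equal(d2 - d1, 20 * log10(2))
  expect_equal(psnr(p$gt, p$gt, p$mask), 100)
})

test_that("scatter sampling is seed-reproducible and OLS is exact on exact data", {
  p <- ref_pair(16)
  f1 <- scatter_fit(p$gt, p$gt, p$mask, n = 2000, seed = 9)
  expect_equal(f1$slope, 1)
  expect_equal(f1$intercept, 0)
  f2 <- scatter_fit(0.5 * p$gt + 0.1, p$gt, p$mask, n = 2000, seed = 9)
  expect_equal(f2$slope, 0.5)
  expect_equal(f2$intercept, 0.1)
  # identical seed samples identical positions for different models
  expect_identical(f1$gt, f2$gt)
  f3 <- scatter_fit(p$gt, p$gt, p$mask, n = 2000, seed = 10)
  expect_false(identical(f1$gt, f3$gt))
  expect_error(scatter_fit(p$gt, p$gt, p$mask, n = 1e7, seed = 1), "sample")
  # direct points (1,2),(2,4),(3,6): slope 2, intercept 0
  pts_gt <- array(c(1, 2, 3, 0, 0, 0, 0, 0), c(2, 2, 2))
  pts_rec <- 2 * pts_gt
  msk <- array(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
               c(2, 2, 2))
  f4 <- scatter_fit(pts_rec, pts_gt, msk, n = 3, seed = 1)
  expect_equal(f4$slope, 2)
  expect_equal(f4$intercept, 0)
})

test_that("region statistics erode with the 3^3 structuring element", {
  v <- array(0, c(12, 12, 12))
  lm <- array(0L, c(12, 12, 12))
  lm[2:10, 2:10, 2:10] <- 1L
  v[lm == 1] <- 0.3
  rs <- region_stats(v, lm, erosion = FALSE)
  expect_equal(rs$mean, 0.3)
  expect_equal(rs$sd, 0)
  expect_equal(rs$n_voxels, 9^3)
  rs_er <- region_stats(v, lm, erosion = TRUE)
  expect_equal(rs_er$n_voxels, 7^3)  # one-voxel shell removed
  # a 3x3x3 solid label erodes to a single voxel
  lm2 <- array(0L, c(8, 8, 8))
  lm2[3:5, 3:5, 3:5] <- 2L
  lm2[1, 1, 1] <- 1L
  v2 <- array(rnorm(8^3), c(8, 8, 8))
  expect_warning(rs2 <- region_stats(v2, lm2, erosion = TRUE), "label 1")
  r2 <- rs2[rs2$label == 2, ]
  expect_equal(r2$n_voxels, 1L)
  expect_equal(r2$mean, v2[4, 4, 4])
  # eroded statistics match exhaustive enumeration on an L-shaped label
  lm3 <- array(0L, c(10, 10, 10))
  lm3[2:9, 2:9, 2:6] <- 3L
  lm3[2:5, 2:5, 2:9] <- 3L
  v3 <- array(rnorm(1000), c(10, 10, 10))
  keep <- array(FALSE, dim(lm3))
  for (x in 1:10) for (y in 1:10) for (z in 1:10) {
    if (lm3[x, y, z] != 3) next
    if (x %in% c(1, 10) || y %in% c(1, 10) || z %in% c(1, 10)) next
    block <- lm3[(x - 1):(x + 1), (y - 1):(y + 1), (z - 1):(z + 1)]
    keep[x, y, z] <- all(block == 3)
  }
  rs3 <- region_stats(v3, lm3, erosion = TRUE)
  expect_equal(rs3$n_voxels, sum(keep))
  expect_equal(rs3$mean, mean(v3[keep]))
  expect_equal(rs3$sd, sd(v3[keep]))
})

test_that("referencing to the masked mean is exact and idempotent", {
  p <- ref_pair()
  v <- susceptibility_volume(p$gt + 0.7, acq_geometry(), p$mask)
  r1 <- referencing(v)
  expect_equal(mean(r1$values[p$mask]), 0)
  r2 <- referencing(r1)
  expect_equal(r2$values, r1$values)
  const <- referencing(array(5, c(4, 4, 4)))
  expect_equal(max(abs(const)), 0)
  expect_error(referencing(p$gt, mask = array(FALSE, dim(p$gt))), "empty")
})

test_that("the combined metrics report carries consistent fields", {
  p <- ref_pair(16)
  rec <- p$gt * 0.9 + array(rnorm(16^3, sd = 0.01), c(16, 16, 16))
  lm <- array(0L, c(16, 16, 16)); lm[4:12, 4:12, 4:12] <- 1L
  rep <- metrics_report(rec, p$gt, p$mask, labels = lm, seed = 3)
  expect_s3_class(rep, "metrics_report")
  expect_equal(rep$n_scatter, sum(p$mask))
  expect_lt(abs(rep$slope - 0.9), 0.05)
  expect_true(rep$nrmse > 0 && rep$ssim < 1 && rep$psnr > 0)
  expect_equal(nrow(rep$regions), 1)
  expect_output(print(rep), "NRMSE")
})
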