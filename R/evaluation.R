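#' Normalized root-mean-squared error (percent)
#'
#' `100 * ||rec - gt||_2 / ||gt||_2` over the masked voxels: the root mean
#' squared error divided by the L2 norm of the ground truth, multiplied by
#' 100.
#'
#' @param rec,gt 3D arrays or [qsm_volume] objects of one shape.
#' @param mask Optional logical array restricting the comparison.
#' @return NRMSE in percent (0 for identical inputs).
#' @export
nrmse <- function(rec, gt, mask = NULL) {
  v <- masked_pair(rec, gt, mask)
  den <- sqrt(sum(v$gt^2))
  if (den == 0) stop("NRMSE undefined: ground truth is identically zero in the mask")
  100 * sqrt(sum((v$rec - v$gt)^2)) / den
}

masked_pair <- function(rec, gt, mask) {
  r <- as_volume_values(rec)
  g <- as_volume_values(gt)
  if (!identical(dim(r), dim(g))) stop("shapes must match")
  if (is.null(mask) && inherits(gt, "qsm_volume")) mask <- gt$mask
  if (!is.null(mask)) {
    mask <- as.array(mask) != 0
    if (!identical(dim(mask), dim(r))) stop("mask shape must match")
    list(rec = r[mask], gt = g[mask], mask = mask)
  } else {
    list(rec = as.numeric(r), gt = as.numeric(g), mask = NULL)
  }
}

#' Structural similarity index for 3D volumes
#'
#' Mean SSIM with a Gaussian-weighted 3D window (sd 1.5 voxels, half-width
#' 3, i.e. a 7^3 window) and the standard stabilizers `C1 = (0.01 L)^2`,
#' `C2 = (0.03 L)^2`.  The data range `L` defaults to max - min of the
#' ground truth within the mask.  The SSIM map is averaged over masked
#' voxels.
#'
#' @param rec,gt 3D arrays or volumes of one shape.
#' @param mask Optional logical array.
#' @param data_range Dynamic range `L`; default from the masked ground truth.
#' @param window_sigma,window_halfwidth Gaussian window parameters (voxels).
#' @return SSIM in \[-1, 1\] (1 for identical inputs).
#' @export
ssim3d <- function(rec, gt, mask = NULL, data_range = NULL,
                   window_sigma = 1.5, window_halfwidth = 3) {
  r <- as_volume_values(rec)
  g <- as_volume_values(gt)
  if (!identical(dim(r), dim(g))) stop("shapes must match")
  if (any(2 * window_halfwidth + 1 > dim(r))) {
    stop("SSIM window larger than the volume")
  }
  if (is.null(mask) && inherits(gt, "qsm_volume")) mask <- gt$mask
  if (!is.null(mask)) mask <- as.array(mask) != 0
  if (is.null(data_range)) {
    gv <- if (is.null(mask)) g else g[mask]
    data_range <- max(gv) - min(gv)
    if (data_range == 0) data_range <- 1
  }
  blur <- function(x) gaussian_blur3d_cpp(x, rep(window_sigma, 3),
                                          as.integer(window_halfwidth))
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  mu_r <- blur(r)
  mu_g <- blur(g)
  var_r <- blur(r^2) - mu_r^2
  var_g <- blur(g^2) - mu_g^2
  cov_rg <- blur(r * g) - mu_r * mu_g
  ssim_map <- ((2 * mu_r * mu_g + c1) * (2 * cov_rg + c2)) /
    ((mu_r^2 + mu_g^2 + c1) * (var_r + var_g + c2))
  if (is.null(mask)) mean(ssim_map) else mean(ssim_map[mask])
}

#' Peak signal-to-noise ratio (dB)
#'
#' `10 log10(range^2 / MSE)` over the masked voxels; identical inputs are
#' reported at the cap (default 100 dB).
#'
#' @param rec,gt 3D arrays or volumes of one shape.
#' @param mask Optional logical array.
#' @param data_range Dynamic range; default max - min of the masked ground
#'   truth.
#' @param cap Value reported when MSE is zero.
#' @return PSNR in dB.
#' @export
psnr <- function(rec, gt, mask = NULL, data_range = NULL, cap = 100) {
  v <- masked_pair(rec, gt, mask)
  if (is.null(data_range)) {
    data_range <- max(v$gt) - min(v$gt)
    if (data_range == 0) data_range <- 1
  }
  mse <- mean((v$rec - v$gt)^2)
  if (mse == 0) return(cap)
  min(cap, 10 * log10(data_range^2 / mse))
}

#' Seeded scatter sampling with ordinary least-squares fit
#'
#' Samples `n` voxel positions without replacement from the mask using the
#' given seed (so different models are compared at identical positions) and
#' fits the reconstructed values against the ground truth by unweighted OLS
#' with an intercept, treating the ground truth as exact.
#'
#' @param rec,gt 3D arrays or volumes of one shape.
#' @param mask Optional logical array (defaults to all voxels).
#' @param n Number of sampled positions (reference procedure: 400,000).
#' @param seed Integer seed shared across models.
#' @return List: `slope`, `intercept`, `n`, `seed`, and the sampled values
#'   `rec`, `gt`.
#' @export
scatter_fit <- function(rec, gt, mask = NULL, n = 400000, seed = 1) {
  v <- masked_pair(rec, gt, mask)
  m <- length(v$gt)
  if (n > m) stop(sprintf("cannot sample %d positions from %d masked voxels",
                          n, m))
  pos <- with_local_seed(seed, sample.int(m, n))
  x <- v$gt[pos]
  y <- v$rec[pos]
  fit <- stats::lm.fit(cbind(1, x), y)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       n = n, seed = seed, rec = y, gt = x)
}

#' Per-region statistics with optional erosion
#'
#' Mean and standard deviation of a volume within each labelled region,
#' optionally after one pass of binary erosion with a 3x3x3 all-ones
#' structuring element (shrinking each region by its one-voxel boundary
#' shell, as used for gray-matter label masks).  Regions eroded to nothing
#' are reported as missing with a warning.
#'
#' @param volume 3D array or [qsm_volume] (ppm).
#' @param label_mask Integer 3D array; 0 = background.
#' @param erosion Apply the 3^3 erosion before computing statistics.
#' @return Data frame with columns `label`, `n_voxels`, `mean`, `sd`.
#' @export
region_stats <- function(volume, label_mask, erosion = TRUE) {
  v <- as_volume_values(volume)
  label_mask <- as.array(label_mask)
  if (!identical(dim(v), dim(label_mask))) stop("label mask shape must match")
  labs <- setdiff(sort(unique(as.integer(label_mask))), 0L)
  rows <- lapply(labs, function(l) {
    reg <- label_mask == l
    if (erosion) reg <- erode3(reg)
    n <- sum(reg)
    if (n == 0) {
      warning(sprintf("label %d eroded to empty; reported as missing", l))
      data.frame(label = l, n_voxels = 0L, mean = NA_real_, sd = NA_real_)
    } else {
      data.frame(label = l, n_voxels = n, mean = mean(v[reg]),
                 sd = if (n > 1) stats::sd(v[reg]) else 0)
    }
  })
  do.call(rbind, rows)
}

# binary erosion with a 3x3x3 all-ones structuring element (voxels outside
# the volume count as background)
erode3 <- function(mask) {
  mask <- as.array(mask) != 0
  d <- dim(mask)
  out <- mask
  shift <- function(m, a, s) {
    r <- array(FALSE, d)
    src <- dst <- lapply(d, seq_len)
    if (s == 1) { dst[[a]] <- 2:d[a]; src[[a]] <- 1:(d[a] - 1) }
    else { dst[[a]] <- 1:(d[a] - 1); src[[a]] <- 2:d[a] }
    r[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    r
  }
  for (a in 1:3) {
    out <- out & shift(mask, a, 1) & shift(mask, a, -1)
    mask <- out
  }
  out
}

#' Reference a susceptibility map to its masked mean
#'
#' Subtracts the mean susceptibility within the mask, the standard
#' referencing of susceptibility maps to the average brain-tissue value;
#' idempotent, and the masked mean of the output is exactly zero.
#'
#' @param chi 3D array or [susceptibility_volume()].
#' @param mask Optional logical array (defaults to the volume's mask, or all
#'   voxels); must be non-empty.
#' @return Same type as the input with the offset removed.
#' @export
referencing <- function(chi, mask = NULL) {
  v <- as_volume_values(chi)
  if (is.null(mask) && inherits(chi, "qsm_volume")) mask <- chi$mask
  if (is.null(mask)) mask <- array(TRUE, dim(v))
  mask <- as.array(mask) != 0
  if (!any(mask)) stop("empty mask")
  out <- v - mean(v[mask])
  if (inherits(chi, "qsm_volume")) {
    susceptibility_volume(out, chi$geometry, chi$mask)
  } else {
    out
  }
}

#' Full metrics report for a reconstruction
#'
#' Convenience wrapper computing NRMSE, SSIM, PSNR, the seeded scatter OLS
#' fit and (optionally) per-region statistics in one call.
#'
#' @param rec,gt 3D arrays or volumes of one shape.
#' @param mask Optional logical array.
#' @param labels Optional integer label mask for [region_stats()].
#' @param n_scatter,seed Scatter sampling plan (capped at the masked voxel
#'   count).
#' @return A `metrics_report` list.
#' @export
metrics_report <- function(rec, gt, mask = NULL, labels = NULL,
                           n_scatter = 400000, seed = 1) {
  if (is.null(mask) && inherits(gt, "qsm_volume")) mask <- gt$mask
  nvox <- if (is.null(mask)) length(as_volume_values(gt)) else sum(mask != 0)
  n_scatter <- min(n_scatter, nvox)
  sf <- scatter_fit(rec, gt, mask, n = n_scatter, seed = seed)
  rep <- list(nrmse = nrmse(rec, gt, mask),
              ssim = ssim3d(rec, gt, mask),
              psnr = psnr(rec, gt, mask),
              slope = sf$slope, intercept = sf$intercept,
              n_scatter = n_scatter, seed = seed)
  if (!is.null(labels)) rep$regions <- region_stats(rec, labels)
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("NRMSE %.2f%%  SSIM %.4f  PSNR %.2f dB  slope %.3f  intercept %.4f  (n=%d, seed=%d)\n",
              x$nrmse, x$ssim, x$psnr, x$slope, x$intercept, x$n_scatter,
              x$seed))
  if (!is.null(x$regions)) print(x$regions)
  invisible(x)
}
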