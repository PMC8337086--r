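# Defect-centered cell density from nuclear fluorescence: calibrate the
# integrated intensity of one nucleus, convert summed intensity inside
# circles of radius R into cell counts, and regress density on R.

#' Average single-cell fluorescent intensity
#'
#' Detects nuclei as local maxima above background, randomly samples
#' `n_sample` of them (seeded), and averages their background-subtracted
#' integrated intensities over a disk of radius `3 * spot_sigma`.
#' Background is the image intensity mode.
#'
#' @param image nuclei image matrix
#' @param n_sample nuclei to sample (default 15)
#' @param seed RNG seed for the sample draw
#' @param pixel_size micrometres per pixel
#' @param spot_sigma nucleus spot scale (um), sets the integration disk
#' @return mean integrated intensity per cell (a.u.)
#' @export
single_cell_intensity <- function(image, n_sample = 15L, seed = 1L,
                                  pixel_size = 1, spot_sigma = 4) {
  bg <- intensity_mode(image)
  sig_px <- spot_sigma / pixel_size
  rad <- max(2L, ceiling(3 * sig_px))
  sm <- blur_gaussian(image, max(1, sig_px / 2))
  nr <- nrow(sm); nc <- ncol(sm)
  thr <- bg + 0.1 * (max(sm) - bg)
  # local maxima over a (2k+1)^2 neighbourhood
  k <- max(2L, ceiling(sig_px))
  is_max <- matrix(TRUE, nr, nc)
  for (dr in -k:k) for (dc in -k:k) {
    if (dr == 0 && dc == 0) next
    shifted <- matrix(-Inf, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    shifted[rs - dr, cs - dc] <- sm[rs, cs]
    is_max <- is_max & (sm >= shifted)
  }
  peaks <- which(is_max & sm > thr, arr.ind = TRUE)
  # drop peaks whose integration disk would be clipped
  inb <- peaks[, 1] > rad & peaks[, 1] <= nr - rad &
    peaks[, 2] > rad & peaks[, 2] <= nc - rad
  peaks <- peaks[inb, , drop = FALSE]
  if (nrow(peaks) < n_sample)
    stop(sprintf("only %d detectable nuclei; %d required", nrow(peaks), n_sample))
  set.seed(seed)
  sel <- peaks[sample.int(nrow(peaks), n_sample), , drop = FALSE]
  off <- seq(-rad, rad)
  vals <- vapply(seq_len(n_sample), function(i) {
    patch <- image[sel[i, 1] + off, sel[i, 2] + off]
    sum(patch - bg)
  }, 0)
  mean(vals)
}

#' Cell count and density inside circles of radius R
#'
#' `count_est(R)` is the summed fluorescent intensity inside the circle
#' divided by the single-cell intensity; density is `count / (pi R^2)`
#' reported in cells per mm^2.
#'
#' @param image nuclei image matrix
#' @param center `c(x, y)` circle center in micrometres
#' @param radii circle radii (um), strictly increasing; default 10-350
#' @param cell_intensity a.u. per cell from [single_cell_intensity()]
#' @param pixel_size micrometres per pixel
#' @param timepoint optional label carried into the profile
#' @return a `density_profile` data.frame: `radius_um`, `count_est`,
#'   `density_cells_mm2`, `timepoint`
#' @export
density_vs_radius <- function(image, center, radii = seq(10, 350, by = 20),
                              cell_intensity, pixel_size = 1,
                              timepoint = NA_character_) {
  stopifnot(cell_intensity > 0, all(diff(radii) > 0))
  nr <- nrow(image); nc <- ncol(image)
  xr <- c(0, (nc - 1) * pixel_size); yr <- c(0, (nr - 1) * pixel_size)
  if (center[1] - max(radii) < xr[1] || center[1] + max(radii) > xr[2] ||
      center[2] - max(radii) < yr[1] || center[2] + max(radii) > yr[2])
    stop("largest circle extends beyond the image")
  X <- matrix((seq_len(nc) - 1) * pixel_size, nr, nc, byrow = TRUE)
  Y <- matrix((seq_len(nr) - 1) * pixel_size, nr, nc)
  r2 <- (X - center[1])^2 + (Y - center[2])^2
  counts <- vapply(radii, function(R) sum(image[r2 <= R^2]) / cell_intensity, 0)
  dens <- counts / (pi * radii^2) * 1e6   # um^-2 -> mm^-2
  out <- data.frame(radius_um = radii, count_est = counts,
                    density_cells_mm2 = dens, timepoint = timepoint,
                    stringsAsFactors = FALSE)
  class(out) <- c("density_profile", class(out))
  out
}

#' Slope of density versus radius
#'
#' Ordinary least squares of density (cells/mm^2) on R (um) with a 95%
#' confidence interval from the t distribution. A negative slope means
#' density is higher at the defect core.
#'
#' @param profile a `density_profile` from [density_vs_radius()]
#' @return list `slope` (cells/mm^2 per um), `ci` (length 2), `se`,
#'   `unit = "cells/mm^2/um"`
#' @export
density_slope <- function(profile) {
  stopifnot(nrow(profile) >= 3)
  fit <- linreg_ci(profile$radius_um, profile$density_cells_mm2)
  list(slope = fit$slope, ci = fit$slope_ci, se = fit$slope_se,
       unit = "cells/mm^2/um")
}

#' Compare density values between two timepoints
#'
#' Two-sided Wilcoxon rank-sum test, as used for comparing the density
#' nearest the defects at 0 h versus 10 h.
#'
#' @param values_t0,values_t1 numeric vectors (>= 3 each)
#' @return a `TestResult` list from [rank_sum()]
#' @export
compare_timepoints <- function(values_t0, values_t1) {
  stopifnot(length(values_t0) >= 3, length(values_t1) >= 3)
  rank_sum(values_t0, values_t1)
}
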