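# Angle arithmetic on nematic (theta ~ theta + pi) and circular quantities,
# plus small image helpers shared by several modules.

#' Wrap angles into (-pi, pi]
#' @param a numeric vector of angles (radians)
#' @return angles wrapped to (-pi, pi]
#' @keywords internal
wrap_angle <- function(a) a - 2 * pi * ceiling(a / (2 * pi) - 0.5)

#' Wrap angle differences into (-pi/2, pi/2]
#'
#' The elementary step of nematic winding: a director difference is only
#' defined up to pi, so successive differences are wrapped to the branch
#' closest to zero.
#' @param a numeric vector of angle differences (radians)
#' @return differences wrapped to (-pi/2, pi/2]
#' @keywords internal
wrap_nematic_diff <- function(a) a - pi * ceiling(a / pi - 0.5)

#' Reduce angles to the nematic fundamental domain [0, pi)
#' @param a numeric vector of angles (radians)
#' @return angles mod pi, in [0, pi)
#' @keywords internal
wrap_nematic <- function(a) a %% pi

#' 1-D Gaussian kernel normalized to unit sum
#' @keywords internal
gaussian_kernel1d <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' 1-D derivative-of-Gaussian kernel
#'
#' Scaled so that convolution estimates the true derivative (responds
#' with slope 1 to a unit ramp).
#' @keywords internal
dgauss_kernel1d <- function(sigma, radius = ceiling(4 * sigma)) {
  x <- seq(-radius, radius)
  k <- -x * exp(-x^2 / (2 * sigma^2))
  k / sum(-x * k) * -1
}

# 1-D convolution along rows or columns with replicate boundaries
conv1_replicate <- function(mat, k, along_rows) {
  r <- (length(k) - 1L) / 2L
  n <- if (along_rows) nrow(mat) else ncol(mat)
  idx <- pmin(pmax(seq(1L - r, n + r), 1L), n)
  out <- matrix(0, nrow(mat), ncol(mat))
  if (along_rows) {
    pad <- mat[idx, , drop = FALSE]
    for (j in seq_along(k)) out <- out + k[j] * pad[j:(j + n - 1L), , drop = FALSE]
  } else {
    pad <- mat[, idx, drop = FALSE]
    for (j in seq_along(k)) out <- out + k[j] * pad[, j:(j + n - 1L), drop = FALSE]
  }
  out
}

#' Separable Gaussian blur with replicate (edge-extend) boundaries
#'
#' @param m numeric matrix
#' @param sigma standard deviation in pixels; 0 returns `m` unchanged
#' @return blurred matrix, same dimensions
#' @keywords internal
blur_gaussian <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gaussian_kernel1d(sigma)
  conv1_replicate(conv1_replicate(m, k, TRUE), k, FALSE)
}

#' Gaussian-derivative gradients of an image
#'
#' Separable derivative-of-Gaussian filtering; near-isotropic for
#' sigma >= 1.5, unlike finite differences whose direction-dependent
#' transfer biases orientation estimates toward the diagonal.
#' @param m numeric matrix
#' @param sigma derivative scale in pixels
#' @return list `gx` (along columns), `gy` (along rows)
#' @keywords internal
gradient_gaussian <- function(m, sigma) {
  g <- gaussian_kernel1d(sigma)
  d <- dgauss_kernel1d(sigma)
  list(gx = conv1_replicate(conv1_replicate(m, d, FALSE), g, TRUE),
       gy = conv1_replicate(conv1_replicate(m, d, TRUE), g, FALSE))
}

#' Bilinear interpolation on a matrix
#'
#' Samples `m` at fractional positions given in matrix index units
#' (`row`, `col` with 1-based indexing). Positions outside the matrix
#' return `NA`.
#' @param m numeric matrix
#' @param row,col numeric vectors of fractional indices
#' @return numeric vector of sampled values
#' @keywords internal
interp_bilinear <- function(m, row, col) {
  nr <- nrow(m); nc <- ncol(m)
  out <- rep(NA_real_, length(row))
  ok <- row >= 1 & row <= nr & col >= 1 & col <= nc & is.finite(row) & is.finite(col)
  if (!any(ok)) return(out)
  r <- row[ok]; c <- col[ok]
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0, c0); i10 <- cbind(r0 + 1, c0)
  i01 <- cbind(r0, c0 + 1); i11 <- cbind(r0 + 1, c0 + 1)
  out[ok] <- (1 - fr) * (1 - fc) * m[i00] + fr * (1 - fc) * m[i10] +
    (1 - fr) * fc * m[i01] + fr * fc * m[i11]
  out
}

#' Most frequent intensity value (histogram mode)
#'
#' Used as a background estimate for fluorescence images: in a sparse
#' nuclei image, most pixels are background.
#' @param x numeric vector or matrix
#' @param nbins number of histogram bins
#' @return the center of the fullest bin
#' @keywords internal
intensity_mode <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  rng <- range(x, finite = TRUE)
  if (diff(rng) == 0) return(rng[1])
  h <- graphics::hist(x, breaks = seq(rng[1], rng[2], length.out = nbins + 1L),
                      plot = FALSE)
  h$mids[which.max(h$counts)]
}

# Derive a stream-specific child seed from a scene seed; keeps all
# generators reproducible from one integer without sharing a stream.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(stream) * 7919) %%
               2147483647)
}
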