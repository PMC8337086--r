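# Local orientation from image texture via the structure tensor.
#
# For an elongated-cell image the intensity varies least along the cell
# axis, so the director is the eigenvector of the *smaller* eigenvalue of
# the gradient structure tensor. Coherence (lambda1 - lambda2) /
# (lambda1 + lambda2) plays the role of a local nematic order parameter.

#' Gradient structure tensor of an image
#'
#' Computes derivative-of-Gaussian gradients at scale `gradient_sigma`
#' (near-isotropic, unlike finite differences) and averages the gradient
#' outer products over a Gaussian window of SD `window_sigma`.
#'
#' @param image numeric matrix (y-up frame)
#' @param gradient_sigma pre-smoothing SD in pixels (>= 1)
#' @param window_sigma averaging window SD in pixels (>= gradient_sigma);
#'   the default 16 px is about one cell width at 0.625 um/px
#' @return list of matrices `Jxx`, `Jxy`, `Jyy` (same shape as `image`)
#' @export
structure_tensor <- function(image, gradient_sigma = 2, window_sigma = 16) {
  if (!all(is.finite(image))) stop("image contains non-finite pixels")
  stopifnot(window_sigma >= gradient_sigma, gradient_sigma >= 1)
  g <- gradient_gaussian(image, gradient_sigma)
  list(Jxx = blur_gaussian(g$gx * g$gx, window_sigma),
       Jxy = blur_gaussian(g$gx * g$gy, window_sigma),
       Jyy = blur_gaussian(g$gy * g$gy, window_sigma))
}

#' Director field from structure-tensor grids
#'
#' The director angle is the orientation of the minor eigenvector of J
#' (the direction of least intensity variation, i.e. the streak axis),
#' mapped to \[0, pi). Coherence is (lambda1 - lambda2) / (lambda1 +
#' lambda2), set to 0 where the tensor trace vanishes.
#'
#' @param tensor list with `Jxx`, `Jxy`, `Jyy` from [structure_tensor()]
#' @param pixel_size micrometres per pixel
#' @param stride keep every `stride`-th node in each direction
#' @return an [orientation_field()]
#' @export
director_field <- function(tensor, pixel_size = 1, stride = 1L) {
  Jxx <- tensor$Jxx; Jxy <- tensor$Jxy; Jyy <- tensor$Jyy
  stride <- as.integer(stride)
  stopifnot(stride >= 1)
  ri <- seq(1L, nrow(Jxx), by = stride)
  ci <- seq(1L, ncol(Jxx), by = stride)
  Jxx <- Jxx[ri, ci]; Jxy <- Jxy[ri, ci]; Jyy <- Jyy[ri, ci]
  # major eigenvector angle of J, then + pi/2 for the minor axis
  theta <- wrap_nematic(0.5 * atan2(2 * Jxy, Jxx - Jyy) + pi / 2)
  tr <- Jxx + Jyy
  coh <- sqrt((Jxx - Jyy)^2 + 4 * Jxy^2) / ifelse(tr > 0, tr, 1)
  coh[tr <= .Machine$double.eps * max(tr)] <- 0
  orientation_field(theta, coh,
                    x = (ci - 1) * pixel_size, y = (ri - 1) * pixel_size,
                    pixel_size = pixel_size)
}

#' Estimate a director field directly from an image
#'
#' Convenience wrapper: [structure_tensor()] then [director_field()].
#' @inheritParams structure_tensor
#' @inheritParams director_field
#' @return an [orientation_field()]
#' @export
estimate_director <- function(image, pixel_size = 1, gradient_sigma = 2,
                              window_sigma = 16, stride = 1L) {
  director_field(structure_tensor(image, gradient_sigma, window_sigma),
                 pixel_size = pixel_size, stride = stride)
}

#' Downsample an orientation field on the nematic tensor
#'
#' Block-averages the coherence-weighted nematic tensor (cos 2 theta,
#' sin 2 theta) -- never raw angles, which would break the theta ~
#' theta + pi symmetry -- and re-extracts the angle.
#'
#' @param field an [orientation_field()]
#' @param factor integer block size >= 1
#' @return an [orientation_field()] with `floor(dim / factor)` nodes
#' @export
downsample_field <- function(field, factor) {
  factor <- as.integer(factor)
  stopifnot(inherits(field, "orientation_field"), factor >= 1)
  nr <- nrow(field$theta); nc <- ncol(field$theta)
  if (factor > min(nr, nc)) stop("downsampling factor larger than the grid")
  if (factor == 1) return(field)
  nrow_out <- nr %/% factor; ncol_out <- nc %/% factor
  block_mean <- function(m) {
    m <- m[seq_len(nrow_out * factor), seq_len(ncol_out * factor), drop = FALSE]
    m <- array(m, c(factor, nrow_out, factor * ncol_out))
    m <- apply(m, c(2, 3), mean)
    m <- array(m, c(nrow_out, factor, ncol_out))
    apply(m, c(1, 3), mean)
  }
  w <- field$coherence
  qc <- block_mean(w * cos(2 * field$theta))
  qs <- block_mean(w * sin(2 * field$theta))
  wm <- block_mean(w)
  theta <- wrap_nematic(0.5 * atan2(qs, qc))
  coh <- pmin(sqrt(qc^2 + qs^2) / ifelse(wm > 0, wm, 1), 1)
  coh[wm <= 0] <- 0
  xi <- vapply(seq_len(ncol_out),
               function(j) mean(field$x[((j - 1) * factor + 1):(j * factor)]),
               0)
  yi <- vapply(seq_len(nrow_out),
               function(i) mean(field$y[((i - 1) * factor + 1):(i * factor)]),
               0)
  orientation_field(theta, coh, x = xi, y = yi, pixel_size = field$pixel_size)
}

# Nematic-aware bilinear sampling of a director field at arbitrary
# positions (um). Interpolates the coherence-weighted tensor components.
sample_director <- function(field, x, y) {
  sp <- field_spacing(field)
  col <- (x - field$x[1]) / sp + 1
  row <- (y - field$y[1]) / sp + 1
  w <- field$coherence
  qc <- interp_bilinear(w * cos(2 * field$theta), row, col)
  qs <- interp_bilinear(w * sin(2 * field$theta), row, col)
  list(theta = wrap_nematic(0.5 * atan2(qs, qc)),
       coherence = sqrt(qc^2 + qs^2) /
         pmax(interp_bilinear(w, row, col), .Machine$double.eps))
}
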