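# Grid containers for director and velocity fields.
#
# Both classes use a mathematical ("y-up") frame: matrix row i holds
# y = y[i], column j holds x = x[j], with y increasing with row index and
# angles measured counterclockwise from the +x axis. Images loaded from
# disk (row 1 = top) are flipped on load so that the counterclockwise-
# positive sign convention for angular velocity is unambiguous.

#' Director (orientation) field
#'
#' A grid of headless orientations theta in \[0, pi) with a per-node
#' coherence (order parameter) in \[0, 1\].
#'
#' @param theta matrix of angles (radians); reduced mod pi on construction
#' @param coherence matrix in \[0, 1\], same shape as `theta`
#' @param x,y node coordinates in micrometres (lengths `ncol(theta)` and
#'   `nrow(theta)`); must be strictly increasing and evenly spaced
#' @param pixel_size micrometres per original image pixel
#' @return an `orientation_field` object
#' @export
orientation_field <- function(theta, coherence = NULL, x = NULL, y = NULL,
                              pixel_size = 1) {
  theta <- as.matrix(theta)
  if (is.null(coherence)) coherence <- matrix(1, nrow(theta), ncol(theta))
  coherence <- as.matrix(coherence)
  stopifnot(all(dim(theta) == dim(coherence)),
            all(is.finite(theta)), all(coherence >= -1e-12 & coherence <= 1 + 1e-12))
  if (is.null(x)) x <- (seq_len(ncol(theta)) - 1) * pixel_size
  if (is.null(y)) y <- (seq_len(nrow(theta)) - 1) * pixel_size
  stopifnot(length(x) == ncol(theta), length(y) == nrow(theta))
  structure(list(theta = wrap_nematic(theta),
                 coherence = pmin(pmax(coherence, 0), 1),
                 x = as.numeric(x), y = as.numeric(y),
                 pixel_size = pixel_size),
            class = "orientation_field")
}

#' @export
print.orientation_field <- function(x, ...) {
  cat(sprintf("<orientation_field> %d x %d nodes, spacing %.3g um, mean coherence %.3f\n",
              nrow(x$theta), ncol(x$theta), field_spacing(x), mean(x$coherence)))
  invisible(x)
}

#' Velocity field
#'
#' A grid of 2-vector velocities in micrometres per hour with a validity
#' mask; masked nodes are excluded from all averages.
#'
#' @param vx,vy matrices of velocity components (um/h)
#' @param x,y node coordinates (um)
#' @param frame_interval time between correlated frames (h)
#' @param mask logical matrix, `TRUE` where the node is valid
#' @return a `velocity_field` object
#' @export
velocity_field <- function(vx, vy, x = NULL, y = NULL, frame_interval = 1,
                           mask = NULL) {
  vx <- as.matrix(vx); vy <- as.matrix(vy)
  stopifnot(all(dim(vx) == dim(vy)))
  if (is.null(mask)) mask <- is.finite(vx) & is.finite(vy)
  stopifnot(all(dim(mask) == dim(vx)))
  if (is.null(x)) x <- seq_len(ncol(vx)) - 1
  if (is.null(y)) y <- seq_len(nrow(vx)) - 1
  stopifnot(length(x) == ncol(vx), length(y) == nrow(vx))
  structure(list(vx = vx, vy = vy, x = as.numeric(x), y = as.numeric(y),
                 frame_interval = frame_interval, mask = mask),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  sp <- mean(x$vx[x$mask]^2 + x$vy[x$mask]^2)
  cat(sprintf("<velocity_field> %d x %d nodes, %d valid, rms speed %.3g um/h\n",
              nrow(x$vx), ncol(x$vx), sum(x$mask), sqrt(sp)))
  invisible(x)
}

# grid spacing in um (assumes even spacing, as constructed)
field_spacing <- function(field) {
  if (length(field$x) > 1) diff(field$x[1:2]) else field$pixel_size
}

# coordinate matrices (um) matching the field's theta/vx layout
field_coords <- function(field) {
  nr <- length(field$y); nc <- length(field$x)
  list(x = matrix(field$x, nr, nc, byrow = TRUE),
       y = matrix(field$y, nr, nc))
}

#' Flip an image matrix into the package's y-up frame
#'
#' TIFF readers return row 1 as the top image row; analysis here uses a
#' mathematical frame with y increasing upward so that counterclockwise
#' angular velocity is positive.
#' @param img numeric matrix as read from disk
#' @return the matrix with rows reversed
#' @export
flip_image <- function(img) img[rev(seq_len(nrow(img))), , drop = FALSE]
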