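# Velocity from image pairs by subset cross-correlation, and the
# defect-centered summaries used in the velocity analyses: left/right/
# top/bottom boxes around +1/2 defects, A/B angular sectors and on-/off-
# leg radial averages around -1/2 defects, and matched control boxes.

#' Subset-correlation (PIV) displacement between two images
#'
#' Zero-normalized circular cross-correlation of 64 x 64 pixel subsets on
#' a 16-pixel grid (defaults), with a three-point Gaussian subpixel peak
#' fit per axis. Displacements are converted to velocity by
#' `pixel_size / frame_interval`. Subsets whose correlation peak is below
#' `peak_min`, sits on the search border, or which have (near-)constant
#' intensity are masked invalid.
#'
#' @param imgA,imgB numeric matrices of equal shape (y-up frame), at
#'   least twice the subset size
#' @param subset_px correlation subset size (pixels, power of 2 advised)
#' @param spacing_px node spacing (pixels); 16 px = 10 um at the default
#'   pixel size
#' @param pixel_size micrometres per pixel
#' @param frame_interval hours between the frames
#' @param peak_min minimum acceptable correlation peak
#' @return a [velocity_field()]; attribute `"peak"` holds the peak map
#' @export
piv_displacement <- function(imgA, imgB, subset_px = 64L, spacing_px = 16L,
                             pixel_size = 0.625, frame_interval = 1 / 6,
                             peak_min = 0.3) {
  stopifnot(all(dim(imgA) == dim(imgB)),
            nrow(imgA) >= 2 * subset_px, ncol(imgA) >= 2 * subset_px)
  nr <- nrow(imgA); nc <- ncol(imgA)
  half <- subset_px %/% 2L
  centers_r <- seq(half, nr - half, by = spacing_px)
  centers_c <- seq(half, nc - half, by = spacing_px)
  vx <- matrix(NA_real_, length(centers_r), length(centers_c))
  vy <- vx; peak <- vx
  mask <- matrix(FALSE, length(centers_r), length(centers_c))
  for (i in seq_along(centers_r)) {
    rs <- (centers_r[i] - half + 1L):(centers_r[i] + half)
    for (j in seq_along(centers_c)) {
      cs <- (centers_c[j] - half + 1L):(centers_c[j] + half)
      a <- imgA[rs, cs]; b <- imgB[rs, cs]
      sa <- stats::sd(a); sb <- stats::sd(b)
      if (!is.finite(sa) || !is.finite(sb) || sa < 1e-12 || sb < 1e-12) next
      a0 <- a - mean(a); b0 <- b - mean(b)
      cc <- Re(stats::fft(Conj(stats::fft(a0)) * stats::fft(b0), inverse = TRUE))
      n_px <- length(a0)
      cc <- cc / (n_px * (n_px - 1) * sa * sb)
      pk <- which.max(cc)
      pr <- (pk - 1L) %% subset_px + 1L
      pc <- (pk - 1L) %/% subset_px + 1L
      pv <- cc[pr, pc]
      # shift, with wraparound for negative displacements
      dy <- pr - 1L; if (dy > half) dy <- dy - subset_px
      dx <- pc - 1L; if (dx > half) dx <- dx - subset_px
      if (pv < peak_min || abs(dy) >= half - 1L || abs(dx) >= half - 1L) {
        peak[i, j] <- pv
        next
      }
      # Gaussian subpixel fit: 2-D log-paraboloid over the 3x3 peak
      # neighbourhood (circular indexing); handles the elongated,
      # tilted peaks produced by streaked cell textures
      nbr <- (pr + c(-1L, 0L, 1L) - 1L) %% subset_px + 1L
      nbc <- (pc + c(-1L, 0L, 1L) - 1L) %% subset_px + 1L
      c9 <- cc[nbr, nbc]
      if (all(c9 > 0) && which.max(c9) == 5L) {
        off <- fit_log_paraboloid(log(c9))
        if (all(abs(off) < 1)) { dy <- dy + off[1]; dx <- dx + off[2] }
      }
      vx[i, j] <- dx * pixel_size / frame_interval
      vy[i, j] <- dy * pixel_size / frame_interval
      peak[i, j] <- pv
      mask[i, j] <- TRUE
    }
  }
  out <- velocity_field(vx, vy,
                        x = (centers_c - 1) * pixel_size,
                        y = (centers_r - 1) * pixel_size,
                        frame_interval = frame_interval, mask = mask)
  attr(out, "peak") <- peak
  out
}

# Peak offset (row, col) of a quadratic surface fit to a 3x3 patch of
# log-correlation values; solves the stationary point of
# a + b*x + c*y + d*x^2 + e*x*y + f*y^2 fitted by least squares.
fit_log_paraboloid <- local({
  g <- expand.grid(y = -1:1, x = -1:1)
  X <- cbind(1, g$x, g$y, g$x^2, g$x * g$y, g$y^2)
  P <- solve(crossprod(X), t(X))
  function(L) {
    co <- P %*% as.vector(L)
    H <- matrix(c(2 * co[4], co[5], co[5], 2 * co[6]), 2)
    if (abs(det(H)) < 1e-12) return(c(0, 0))
    sol <- -solve(H, c(co[2], co[3]))   # (x, y) offset
    c(sol[2], sol[1])                    # return (row, col) = (y, x)
  }
})

#' Rotate a velocity field into a defect frame
#'
#' Translates the origin to `center` and rotates positions *and* vectors
#' by `-tail_angle`, so the comet tail points along +x in the output.
#' The field is resampled onto a regular grid by bilinear interpolation;
#' invalid nodes propagate through the interpolation.
#'
#' @param field a [velocity_field()]
#' @param center `c(x, y)` of the defect core (um)
#' @param tail_angle tail direction in the lab frame (radians)
#' @param half_extent half-size of the output grid (um); defaults to the
#'   largest span that keeps the grid within the input data
#' @param spacing output node spacing (um); defaults to the input spacing
#' @return a [velocity_field()] centred on the defect (origin at core)
#' @export
rotate_frame <- function(field, center, tail_angle, half_extent = NULL,
                         spacing = NULL) {
  if (is.null(spacing)) spacing <- field$x[2] - field$x[1]
  if (is.null(half_extent))
    half_extent <- max(max(field$x) - min(field$x),
                       max(field$y) - min(field$y)) / 2
  g <- seq(-half_extent, half_extent, by = spacing)
  Xp <- matrix(g, length(g), length(g), byrow = TRUE)
  Yp <- matrix(g, length(g), length(g))
  ct <- cos(tail_angle); st <- sin(tail_angle)
  # lab position of each defect-frame node
  Xl <- center[1] + ct * Xp - st * Yp
  Yl <- center[2] + st * Xp + ct * Yp
  sp_in <- field$x[2] - field$x[1]
  col <- (Xl - field$x[1]) / sp_in + 1
  row <- (Yl - field$y[1]) / (field$y[2] - field$y[1]) + 1
  vxm <- field$vx; vym <- field$vy
  vxm[!field$mask] <- NA; vym[!field$mask] <- NA
  vx_l <- matrix(interp_bilinear(vxm, as.vector(row), as.vector(col)),
                 length(g), length(g))
  vy_l <- matrix(interp_bilinear(vym, as.vector(row), as.vector(col)),
                 length(g), length(g))
  # rotate vectors into the defect frame
  vx_d <- ct * vx_l + st * vy_l
  vy_d <- -st * vx_l + ct * vy_l
  mask <- is.finite(vx_d) & is.finite(vy_d)
  vx_d[!mask] <- NA; vy_d[!mask] <- NA
  velocity_field(vx_d, vy_d, x = g, y = g,
                 frame_interval = field$frame_interval, mask = mask)
}

box_mean <- function(field, xlim, ylim) {
  cm <- field_coords(field)
  sel <- field$mask & cm$x >= xlim[1] & cm$x <= xlim[2] &
    cm$y >= ylim[1] & cm$y <= ylim[2]
  n <- sum(sel)
  data.frame(mean_vx = if (n) mean(field$vx[sel]) else NA_real_,
             mean_vy = if (n) mean(field$vy[sel]) else NA_real_,
             n_nodes = n, flagged = n < 10)
}

#' Box averages around a +1/2 defect
#'
#' In the defect frame (tail along +x), averages velocity in four
#' rectangular boxes immediately left, right, top, and bottom of the
#' core. Left/right boxes are `box_w` wide by `box_h` tall with inner
#' edges `gap / 2` from the core (so the two regions are `gap` apart);
#' top/bottom boxes are transposed. Boxes with fewer than 10 valid nodes
#' are flagged.
#'
#' @param field a [velocity_field()] in the defect frame (core at origin)
#' @param box_w,box_h box width and height (um); defaults 500 x 750
#' @param gap separation between opposing boxes (um)
#' @return data.frame, one row per box: `box`, `mean_vx`, `mean_vy`,
#'   `n_nodes`, `flagged`
#' @export
plus_half_boxes <- function(field, box_w = 500, box_h = 750, gap = 50) {
  h <- gap / 2
  rows <- rbind(
    cbind(box = "left", box_mean(field, c(-h - box_w, -h), c(-box_h / 2, box_h / 2))),
    cbind(box = "right", box_mean(field, c(h, h + box_w), c(-box_h / 2, box_h / 2))),
    cbind(box = "bottom", box_mean(field, c(-box_h / 2, box_h / 2), c(-h - box_w, -h))),
    cbind(box = "top", box_mean(field, c(-box_h / 2, box_h / 2), c(h, h + box_w))))
  rownames(rows) <- NULL
  rows
}

#' Radial and angular velocity components about a center
#'
#' `v_r = v . rhat`, `v_phi = v . phihat` with the angular unit vector
#' counterclockwise, so counterclockwise motion is positive. The node at
#' the center (if any) is masked.
#'
#' @param field a [velocity_field()]
#' @param center `c(x, y)` in micrometres
#' @return list of matrices `v_r`, `v_phi`, plus `r`, `phi` node
#'   coordinates and the combined validity `mask`
#' @export
polar_components <- function(field, center = c(0, 0)) {
  cm <- field_coords(field)
  dx <- cm$x - center[1]; dy <- cm$y - center[2]
  r <- sqrt(dx^2 + dy^2)
  phi <- atan2(dy, dx)
  mask <- field$mask & r > 0
  cphi <- ifelse(r > 0, dx / r, 0); sphi <- ifelse(r > 0, dy / r, 0)
  v_r <- field$vx * cphi + field$vy * sphi
  v_phi <- -field$vx * sphi + field$vy * cphi
  v_r[!mask] <- NA; v_phi[!mask] <- NA
  list(v_r = v_r, v_phi = v_phi, r = r, phi = phi, mask = mask)
}

#' Sector averages around a -1/2 defect
#'
#' Splits the annulus `r_min < r <= r_max` by the three legs into six
#' sectors labeled alternately A and B: A is the half-sector from which
#' the nearest leg lies counterclockwise, so that flow converging on the
#' legs gives positive (counterclockwise) mean angular velocity in A and
#' negative in B. Nodes within `leg_halfwidth` perpendicular distance of
#' a leg ray are the "on-leg" band, excluded from the angular averages;
#' radial velocity is averaged separately on- and off-leg.
#'
#' @param polar output of [polar_components()] at the defect core
#' @param leg_angles the three leg directions (radians, lab frame)
#' @param r_min inner exclusion radius (um)
#' @param leg_halfwidth half-width of each leg band (um)
#' @param r_max outer inclusion radius (um)
#' @return list with `v_phi_A`, `v_phi_B`, `v_r_on_leg`, `v_r_off_leg`,
#'   node counts, `flagged` (fewer than 10 valid nodes in a group), and
#'   the per-node `zone` matrix ("A", "B", "leg", "excluded")
#' @export
minus_half_sectors <- function(polar, leg_angles, r_min = 250,
                               leg_halfwidth = 45, r_max = 1800) {
  stopifnot(length(leg_angles) == 3)
  r <- polar$r; phi <- polar$phi
  dl <- vapply(leg_angles, function(L) wrap_angle(phi - L), array(0, dim(phi)))
  dl <- array(dl, c(length(phi), 3))
  nearest <- apply(abs(dl), 1, which.min)
  delta <- dl[cbind(seq_along(nearest), nearest)]
  delta <- matrix(delta, nrow(r), ncol(r))
  on_leg <- r * abs(sin(delta)) <= leg_halfwidth & cos(delta) > 0
  zone <- matrix("excluded", nrow(r), ncol(r))
  inside <- r > r_min & r <= r_max & polar$mask
  # A: nearest leg counterclockwise ahead (delta < 0); B: behind
  zone[inside & on_leg] <- "leg"
  zone[inside & !on_leg & delta < 0] <- "A"
  zone[inside & !on_leg & delta >= 0] <- "B"
  grp <- function(z, m) {
    v <- m[zone == z]
    v <- v[is.finite(v)]
    list(mean = if (length(v)) mean(v) else NA_real_, n = length(v))
  }
  a <- grp("A", polar$v_phi); b <- grp("B", polar$v_phi)
  on <- grp("leg", polar$v_r)
  offsel <- zone %in% c("A", "B")
  voff <- polar$v_r[matrix(offsel, nrow(r), ncol(r))]
  voff <- voff[is.finite(voff)]
  list(v_phi_A = a$mean, v_phi_B = b$mean,
       v_r_on_leg = on$mean,
       v_r_off_leg = if (length(voff)) mean(voff) else NA_real_,
       n_A = a$n, n_B = b$n, n_on_leg = on$n, n_off_leg = length(voff),
       flagged = min(a$n, b$n) < 10, zone = zone)
}

#' Control box averages at defect-free locations
#'
#' Applies the +1/2 box geometry at seeded random locations (no rotation;
#' controls have no tail axis), for comparison with defect-centered
#' averages.
#'
#' @param field a [velocity_field()] (lab frame)
#' @param n_boxes number of control locations
#' @param seed RNG seed for the location draw
#' @param box_w,box_h,gap geometry as in [plus_half_boxes()]
#' @param avoid optional data.frame of defect positions (`x`, `y`); a
#'   margin of `box_w + gap` around each is excluded
#' @return data.frame: `location`, `box`, `mean_vx`, `mean_vy`,
#'   `n_nodes`, `flagged`, `cx`, `cy`
#' @export
control_summary <- function(field, n_boxes, seed = 1L, box_w = 500,
                            box_h = 750, gap = 50, avoid = NULL) {
  ext <- box_w + gap / 2
  xr <- c(min(field$x) + ext, max(field$x) - ext)
  yr <- c(min(field$y) + ext, max(field$y) - ext)
  if (xr[1] >= xr[2] || yr[1] >= yr[2])
    stop("field too small for a defect-free control box")
  set.seed(seed)
  out <- list(); tries <- 0L; placed <- 0L
  while (placed < n_boxes && tries < 200L * n_boxes) {
    tries <- tries + 1L
    cx <- stats::runif(1, xr[1], xr[2]); cy <- stats::runif(1, yr[1], yr[2])
    if (!is.null(avoid) && nrow(avoid) > 0 &&
        any(sqrt((avoid$x - cx)^2 + (avoid$y - cy)^2) < box_w + gap)) next
    placed <- placed + 1L
    shifted <- field
    shifted$x <- field$x - cx; shifted$y <- field$y - cy
    bx <- plus_half_boxes(shifted, box_w, box_h, gap)
    bx$location <- placed; bx$cx <- cx; bx$cy <- cy
    out[[placed]] <- bx
  }
  if (placed < n_boxes) stop("no defect-free region large enough for controls")
  do.call(rbind, out)
}
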