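# Synthetic scenes with planted ground truth: director fields containing
# half-integer defects, elongated-cell textures, defect-driven flow
# templates, nuclei images with controlled density, and clearance scenes.
# Every generator draws all randomness from the seed in its scene_config.

#' Scene configuration
#'
#' @param shape grid shape `c(rows, cols)` in pixels; at least 64 x 64
#' @param pixel_size micrometres per pixel; the default 0.625 makes a
#'   16-pixel PIV spacing equal to 10 um
#' @param seed integer seed from which all of the scene's randomness flows
#' @param noise noise amplitude: radians of director noise for director
#'   scenes, fractional intensity noise for images
#' @param frame_interval time between frames (h); default 10 min
#' @return a `scene_config` list
#' @export
scene_config <- function(shape = c(512L, 512L), pixel_size = 0.625,
                         seed = 1L, noise = 0, frame_interval = 1 / 6) {
  stopifnot(length(shape) == 2, all(shape >= 64), pixel_size > 0,
            noise >= 0, frame_interval > 0)
  structure(list(shape = as.integer(shape), pixel_size = pixel_size,
                 seed = as.integer(seed), noise = noise,
                 frame_interval = frame_interval),
            class = "scene_config")
}

#' A defect to plant in a synthetic director field
#'
#' @param x,y core position in micrometres
#' @param charge +0.5 or -0.5
#' @param phase director offset theta0 in \[0, pi)
#' @return a `planted_defect` list
#' @export
planted_defect <- function(x, y, charge, phase = 0) {
  stopifnot(charge %in% c(0.5, -0.5))
  structure(list(x = x, y = y, charge = charge,
                 phase = wrap_nematic(phase)),
            class = "planted_defect")
}

#' Ideal director field with planted defects
#'
#' Superposes defects additively in the angle (the standard nematic
#' multi-defect construction): theta(r) = sum_i q_i * atan2(y - y_i,
#' x - x_i) + theta0, reduced mod pi, plus optional wrapped-Gaussian
#' noise on the angle. Coherence is set to the nematic order parameter
#' of the noise distribution, exp(-2 sigma^2).
#'
#' @param defects list of [planted_defect()] objects (may be empty);
#'   `phase` values are summed into a single offset
#' @param cfg a [scene_config()]; `cfg$noise` is the angular noise SD
#'   (radians)
#' @return an [orientation_field()] with the planted truth attached as
#'   attribute `"planted"`
#' @export
ideal_director_field <- function(defects, cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  nr <- cfg$shape[1]; nc <- cfg$shape[2]
  xs <- (seq_len(nc) - 1) * cfg$pixel_size
  ys <- (seq_len(nr) - 1) * cfg$pixel_size
  if (length(defects) > 0) {
    px <- vapply(defects, `[[`, numeric(1), "x")
    py <- vapply(defects, `[[`, numeric(1), "y")
    if (any(px < min(xs)) || any(px > max(xs)) ||
        any(py < min(ys)) || any(py > max(ys)))
      stop("planted defect position outside the grid")
    if (length(defects) > 1) {
      d <- as.matrix(stats::dist(cbind(px, py)))
      diag(d) <- Inf
      if (min(d) < 20 * cfg$pixel_size)
        stop("overlapping defect cores: planted defects must be >= 20 px apart")
    }
  }
  X <- matrix(xs, nr, nc, byrow = TRUE)
  Y <- matrix(ys, nr, nc)
  theta <- matrix(0, nr, nc)
  for (d in defects) theta <- theta + d$charge * atan2(Y - d$y, X - d$x) + d$phase
  if (cfg$noise > 0) {
    set.seed(child_seed(cfg$seed, 1L))
    theta <- theta + stats::rnorm(length(theta), 0, cfg$noise)
  }
  coh <- matrix(exp(-2 * cfg$noise^2), nr, nc)
  fld <- orientation_field(theta, coh, x = xs, y = ys,
                           pixel_size = cfg$pixel_size)
  attr(fld, "planted") <- list(defects = defects, noise = cfg$noise)
  fld
}

#' Render an elongated-cell texture aligned with a director field
#'
#' Line-integral-convolution style rendering: seeded white noise is
#' averaged along short straight segments oriented by the local director,
#' producing streaks of length `streak_length` along the planted
#' orientation, as in a phase-contrast image of high-aspect-ratio cells.
#'
#' @param field an [orientation_field()] sampled at pixel resolution
#' @param streak_length streak length in micrometres (>= 2 px equivalent)
#' @param cfg a [scene_config()]; `cfg$noise` adds fractional white noise
#'   to the rendered image
#' @return numeric image matrix (y-up frame), values roughly in \[0, 1\]
#' @export
render_cell_texture <- function(field, streak_length, cfg) {
  stopifnot(inherits(field, "orientation_field"))
  L_px <- streak_length / cfg$pixel_size
  nr <- nrow(field$theta); nc <- ncol(field$theta)
  set.seed(child_seed(cfg$seed, 2L))
  noise_img <- matrix(stats::runif(nr * nc), nr, nc)
  if (L_px < 2) return(noise_img)
  half <- floor(L_px / 2)
  ct <- cos(field$theta); st <- sin(field$theta)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  acc <- matrix(0, nr, nc); wsum <- 0
  for (t in seq(-half, half)) {
    # step along the director: x -> columns, y -> rows
    r <- rows + t * st
    c <- cols + t * ct
    v <- interp_bilinear(noise_img, as.vector(r), as.vector(c))
    v[is.na(v)] <- noise_img[is.na(v)]
    acc <- acc + matrix(v, nr, nc)
    wsum <- wsum + 1
  }
  img <- acc / wsum
  if (cfg$noise > 0) {
    set.seed(child_seed(cfg$seed, 3L))
    img <- img + stats::rnorm(length(img), 0, cfg$noise * stats::sd(img))
  }
  img
}

#' Kinematic flow template around a defect
#'
#' Builds the velocity field used as ground truth for the velocity
#' analyses. In the defect frame of a +1/2 defect (comet tail along +x)
#' the template is `vx = -v0 * sign(x) * exp(-r / decay_length), vy = 0`,
#' i.e. net inward flow along the tail axis from both sides. For a -1/2
#' defect the angular component drives each point toward its nearest leg
#' and the radial component is `+v0 * exp(-r / decay_length)` outside the
#' leg bands and zero on them (leg-convergent, net outward elsewhere).
#'
#' @param defect a list with `x`, `y`, `charge` and either `tail_angle`
#'   (+1/2, radians) or `leg_angles` (-1/2, length 3, radians); a
#'   [planted_defect()] is accepted, with axes derived from its phase
#' @param v0 flow speed scale (um/h); must be >= 0
#' @param decay_length e-folding length of the flow magnitude (um)
#' @param cfg a [scene_config()]
#' @param spacing_px node spacing in pixels (default 16, the PIV spacing)
#' @param leg_halfwidth half-width of the -1/2 leg bands (um)
#' @return a [velocity_field()] in the laboratory frame
#' @export
defect_flow_field <- function(defect, v0, decay_length, cfg,
                              spacing_px = 16L, leg_halfwidth = 45) {
  stopifnot(v0 >= 0, decay_length > 0)
  if (!defect$charge %in% c(0.5, -0.5)) stop("unknown defect charge")
  nr <- cfg$shape[1]; nc <- cfg$shape[2]
  xs <- seq(0, (nc - 1) * cfg$pixel_size, by = spacing_px * cfg$pixel_size)
  ys <- seq(0, (nr - 1) * cfg$pixel_size, by = spacing_px * cfg$pixel_size)
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE) - defect$x
  Y <- matrix(ys, length(ys), length(xs)) - defect$y
  r <- sqrt(X^2 + Y^2)
  amp <- exp(-r / decay_length)
  if (defect$charge > 0) {
    tail <- defect$tail_angle %||% (2 * wrap_nematic(defect$phase) + pi)
    # rotate into the defect frame (tail along +x')
    xp <- cos(-tail) * X - sin(-tail) * Y
    vxp <- -v0 * sign(xp) * amp
    vx <- cos(tail) * vxp
    vy <- sin(tail) * vxp
  } else {
    legs <- defect$leg_angles %||% ((2 / 3) * (wrap_nematic(defect$phase) + pi * 0:2))
    phi <- atan2(Y, X)
    dl <- vapply(legs, function(L) wrap_angle(phi - L), array(0, dim(phi)))
    near <- apply(abs(dl), c(1, 2), which.min)
    delta <- array(dl, c(length(dl) / 3, 3))[cbind(seq_along(near), as.vector(near))]
    delta <- matrix(delta, nrow(phi), ncol(phi))
    on_leg <- r * abs(sin(delta)) <= leg_halfwidth & cos(delta) > 0
    vphi <- -v0 * sign(delta) * amp          # toward the nearest leg
    vr <- ifelse(on_leg, 0, v0 * amp)        # net outward off the legs
    vx <- vr * cos(phi) - vphi * sin(phi)
    vy <- vr * sin(phi) + vphi * cos(phi)
  }
  center_node <- r == 0
  vx[center_node] <- 0; vy[center_node] <- 0
  velocity_field(vx, vy, x = xs, y = ys, frame_interval = cfg$frame_interval)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Warp an image by a displacement field
#'
#' Produces the second frame of a PIV ground-truth pair: the output at
#' position p equals the input at p - d(p), so features move by +d from
#' the first frame to the second. Displacements are bilinear-interpolated
#' samples; pixels whose source falls outside the image are filled with
#' the nearest edge value and marked invalid in the `"valid"` attribute.
#'
#' @param image numeric matrix
#' @param dx,dy displacement in pixels, either scalars or matrices of the
#'   image's shape
#' @param max_disp largest magnitude allowed (guard so PIV subsets can
#'   still capture the motion); default 32 px = half a 64 px subset
#' @return warped image matrix with attribute `valid` (logical matrix)
#' @export
advect_image <- function(image, dx, dy, max_disp = 32) {
  nr <- nrow(image); nc <- ncol(image)
  if (length(dx) == 1) dx <- matrix(dx, nr, nc)
  if (length(dy) == 1) dy <- matrix(dy, nr, nc)
  if (max(abs(dx), abs(dy)) >= max_disp)
    stop("displacement exceeds half the correlation subset size")
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  src_r <- rows - dy   # y -> rows in the y-up frame
  src_c <- cols - dx
  v <- interp_bilinear(image, as.vector(src_r), as.vector(src_c))
  valid <- matrix(!is.na(v), nr, nc)
  v[is.na(v)] <- interp_bilinear(image,
                                 pmin(pmax(as.vector(src_r), 1), nr),
                                 pmin(pmax(as.vector(src_c), 1), nc))[is.na(v)]
  out <- matrix(v, nr, nc)
  attr(out, "valid") <- valid
  out
}

#' Synthetic nuclei image with controlled density
#'
#' Places nuclei by an inhomogeneous Poisson point process (thinning) and
#' renders each as a Gaussian spot whose integrated intensity equals
#' `intensity_per_cell`, emulating a DAPI-stained field.
#'
#' @param density_fn function(x_um, y_um) -> cells per mm^2 (vectorized,
#'   must be >= 0 everywhere), or a single number for uniform density
#' @param spot_sigma Gaussian spot SD in micrometres
#' @param intensity_per_cell integrated intensity per nucleus (a.u.)
#' @param cfg a [scene_config()]; `cfg$noise` adds fractional Gaussian
#'   read noise
#' @return list with `image` (matrix), `positions` (data.frame x, y in um)
#' @export
nuclei_image <- function(density_fn, spot_sigma, intensity_per_cell, cfg) {
  nr <- cfg$shape[1]; nc <- cfg$shape[2]
  w_um <- nc * cfg$pixel_size; h_um <- nr * cfg$pixel_size
  if (is.numeric(density_fn)) {
    dens0 <- density_fn
    density_fn <- function(x, y) rep(dens0, length(x))
  }
  # peak intensity of the process, probed on a coarse grid
  gx <- seq(0, w_um, length.out = 32)
  gy <- seq(0, h_um, length.out = 32)
  gg <- expand.grid(x = gx, y = gy)
  lam <- density_fn(gg$x, gg$y)
  if (any(lam < 0)) stop("density_fn must be non-negative everywhere")
  lam_max <- max(lam) * 1.05 + 1e-12
  set.seed(child_seed(cfg$seed, 4L))
  area_mm2 <- (w_um / 1000) * (h_um / 1000)
  n_cand <- stats::rpois(1, lam_max * area_mm2)
  img <- matrix(0, nr, nc)
  pos <- data.frame(x = numeric(0), y = numeric(0))
  if (n_cand > 0) {
    cx <- stats::runif(n_cand, 0, w_um)
    cy <- stats::runif(n_cand, 0, h_um)
    keep <- stats::runif(n_cand) < density_fn(cx, cy) / lam_max
    cx <- cx[keep]; cy <- cy[keep]
    pos <- data.frame(x = cx, y = cy)
    sig_px <- spot_sigma / cfg$pixel_size
    rad <- max(2L, ceiling(3 * sig_px))
    off <- seq(-rad, rad)
    for (i in seq_along(cx)) {
      pc <- cx[i] / cfg$pixel_size + 1   # column, 1-based
      pr <- cy[i] / cfg$pixel_size + 1
      rr <- round(pr) + off; cc <- round(pc) + off
      kr <- exp(-(rr - pr)^2 / (2 * sig_px^2))
      kc <- exp(-(cc - pc)^2 / (2 * sig_px^2))
      kern <- outer(kr, kc)
      kern <- kern / sum(kern) * intensity_per_cell
      rok <- rr >= 1 & rr <= nr; cok <- cc >= 1 & cc <= nc
      img[rr[rok], cc[cok]] <- img[rr[rok], cc[cok]] + kern[rok, cok]
    }
  }
  if (cfg$noise > 0) {
    set.seed(child_seed(cfg$seed, 5L))
    img <- img + stats::rnorm(length(img), 0, cfg$noise * intensity_per_cell /
                                (2 * pi * (spot_sigma / cfg$pixel_size)^2))
    img[img < 0] <- 0
  }
  list(image = img, positions = pos)
}

#' Synthetic clearance scene
#'
#' Two-channel mask stack emulating a spheroid-induced clearance assay:
#' the spheroid channel holds a disk of constant area and the mesothelial
#' channel holds a monolayer with a growing circular hole whose area
#' increases linearly at `clear_rate`. The analytic areas used to draw
#' each frame are returned as a table alongside the rendered masks.
#'
#' @param spheroid_area0 spheroid area (um^2), constant over time
#' @param clear_rate cleared-area growth rate (um^2 / h), >= 0
#' @param n_frames number of frames (>= 3)
#' @param cfg a [scene_config()]; `cfg$noise` is the SD of fractional
#'   area noise applied to the cleared region frame by frame
#' @param dt frame interval in hours (default 1, hourly imaging)
#' @return list with `spheroid` and `mesothelium` (stacks as lists of
#'   matrices), `areas` (data.frame time_h, spheroid_area, cleared_area),
#'   `pixel_size`
#' @export
clearance_scene <- function(spheroid_area0, clear_rate, n_frames, cfg, dt = 1) {
  stopifnot(clear_rate >= 0, n_frames >= 3, spheroid_area0 > 0)
  nr <- cfg$shape[1]; nc <- cfg$shape[2]
  ps <- cfg$pixel_size
  cx <- (nc - 1) / 2 * ps; cy <- (nr - 1) / 2 * ps
  X <- matrix((seq_len(nc) - 1) * ps, nr, nc, byrow = TRUE)
  Y <- matrix((seq_len(nr) - 1) * ps, nr, nc)
  r2 <- (X - cx)^2 + (Y - cy)^2
  times <- (seq_len(n_frames) - 1) * dt
  set.seed(child_seed(cfg$seed, 6L))
  eps <- if (cfg$noise > 0) stats::rnorm(n_frames, 0, cfg$noise) else rep(0, n_frames)
  r_sph <- sqrt(spheroid_area0 / pi)
  sph_mask <- r2 <= r_sph^2
  spheroid <- vector("list", n_frames)
  mesoth <- vector("list", n_frames)
  cleared_true <- clear_rate * times
  cleared_drawn <- pmax(cleared_true * (1 + eps), 0)
  for (k in seq_len(n_frames)) {
    rc <- sqrt(cleared_drawn[k] / pi)
    spheroid[[k]] <- sph_mask + 0
    mesoth[[k]] <- (r2 > rc^2) + 0
  }
  areas <- data.frame(time_h = times,
                      spheroid_area = rep(spheroid_area0, n_frames),
                      cleared_area = cleared_drawn)
  list(spheroid = spheroid, mesothelium = mesoth, areas = areas,
       pixel_size = ps, center = c(x = cx, y = cy),
       planted = list(rate = clear_rate, area0 = spheroid_area0))
}
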