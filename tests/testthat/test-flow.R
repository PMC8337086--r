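# PIV displacement recovery and defect-frame velocity summaries.

test_that("PIV recovers planted uniform shifts", {
  sc <- make_texture_scene(noise = 0.15)
  # integer shift: 3 px at 0.625 um/px over 10 min -> 11.25 um/h
  b <- advect_image(sc$tex, 3, 0)
  v <- piv_displacement(sc$tex, b)
  expect_equal(mean(v$vx[v$mask]), 11.25, tolerance = 0.75 / 11.25)
  expect_lt(abs(mean(v$vy[v$mask])), 0.75)
  # identical images: zero field
  v0 <- piv_displacement(sc$tex, sc$tex)
  expect_equal(max(abs(v0$vx[v0$mask]), abs(v0$vy[v0$mask])), 0)
  # subpixel shifts recovered within 0.2 px per component
  for (sh in list(c(2.5, 0), c(2.5, -1.25), c(0.5, 0.25))) {
    b2 <- advect_image(sc$tex, sh[1], sh[2])
    v2 <- piv_displacement(sc$tex, b2)
    px <- (1 / 6) / 0.625
    expect_lt(abs(mean(v2$vx[v2$mask]) * px - sh[1]), 0.2)
    expect_lt(abs(mean(v2$vy[v2$mask]) * px - sh[2]), 0.2)
  }
})

test_that("constant subsets are masked rather than erroring", {
  flat <- matrix(1, 160, 160)
  v <- piv_displacement(flat, flat)
  expect_equal(sum(v$mask), 0L)
})

test_that("polar components satisfy the energy split identity", {
  set.seed(8)
  v <- velocity_field(matrix(stats::rnorm(400), 20), matrix(stats::rnorm(400), 20),
                      x = seq(0, 190, by = 10), y = seq(0, 190, by = 10))
  pol <- polar_components(v, c(95, 95))
  ok <- pol$mask
  expect_lt(max(abs(pol$v_r[ok]^2 + pol$v_phi[ok]^2 -
                      (v$vx[ok]^2 + v$vy[ok]^2))), 1e-9)
  # pure radial outflow: v_phi = 0, v_r > 0
  cm <- list(x = matrix(v$x, 20, 20, byrow = TRUE) - 95,
             y = matrix(v$y, 20, 20) - 95)
  r <- sqrt(cm$x^2 + cm$y^2); r[r == 0] <- 1
  vr <- velocity_field(cm$x / r, cm$y / r, x = v$x, y = v$y)
  pr <- polar_components(vr, c(95, 95))
  expect_lt(max(abs(pr$v_phi[pr$mask])), 1e-9)
  expect_gt(min(pr$v_r[pr$mask]), 0)
  # rigid counterclockwise rotation: v_phi = omega * r, v_r = 0
  om <- 0.05
  vrot <- velocity_field(-om * cm$y, om * cm$x, x = v$x, y = v$y)
  pt <- polar_components(vrot, c(95, 95))
  expect_lt(max(abs(pt$v_r[pt$mask])), 1e-9)
  expect_equal(pt$v_phi[pt$mask], (om * r)[pt$mask], tolerance = 1e-9)
})

test_that("rotate_frame is a proper rigid motion of positions and vectors", {
  # pure +x flow rotated by pi/2 becomes pure +y flow
  v <- velocity_field(matrix(5, 21, 21), matrix(0, 21, 21),
                      x = seq(-100, 100, by = 10), y = seq(-100, 100, by = 10))
  r <- rotate_frame(v, c(0, 0), pi / 2, half_extent = 60)
  ok <- r$mask
  expect_lt(max(abs(r$vx[ok])), 1e-9)
  expect_equal(unique(round(r$vy[ok], 9)), -5)
  # tail already at 0: identity up to interpolation
  rid <- rotate_frame(v, c(0, 0), 0, half_extent = 60)
  expect_equal(rid$vx[rid$mask], rep(5, sum(rid$mask)), tolerance = 1e-9)
  # round trip pi then pi restores the field
  r1 <- rotate_frame(v, c(0, 0), pi, half_extent = 80)
  r2 <- rotate_frame(r1, c(0, 0), pi, half_extent = 60)
  expect_equal(r2$vx[r2$mask], rep(5, sum(r2$mask)), tolerance = 1e-6)
})

test_that("plus-half boxes reproduce the template's box-averaged closed form", {
  # planted template vx = -v0 sign(x) exp(-r/lambda) on a fine grid
  v0 <- 10; lam <- 500
  g <- seq(-1300, 1300, by = 10)
  X <- matrix(g, length(g), length(g), byrow = TRUE)
  Y <- matrix(g, length(g), length(g))
  R <- sqrt(X^2 + Y^2)
  fld <- velocity_field(-v0 * sign(X) * exp(-R / lam), 0 * X, x = g, y = g)
  bx <- plus_half_boxes(fld)
  # independent quadrature of the template over the right box
  xs <- seq(25, 525, length.out = 201); ys <- seq(-375, 375, length.out = 301)
  integrand <- outer(ys, xs, function(y, x) -v0 * exp(-sqrt(x^2 + y^2) / lam))
  oracle <- mean(integrand)
  got <- bx$mean_vx[bx$box == "right"]
  expect_equal(got, oracle, tolerance = 0.05)
  expect_equal(bx$mean_vx[bx$box == "left"], -oracle, tolerance = 0.05)
  expect_lt(abs(bx$mean_vx[bx$box == "top"]), abs(oracle))
  expect_false(any(bx$flagged))
  # zero field: all means zero
  z <- velocity_field(0 * X, 0 * X, x = g, y = g)
  expect_equal(plus_half_boxes(z)$mean_vx, rep(0, 4))
})

test_that("sign pattern at +1/2: inward flow on both sides of the tail", {
  cfg <- scene_config(shape = c(1024L, 1024L), pixel_size = 2, seed = 1L)
  ctr <- 1023
  fp <- defect_flow_field(list(x = ctr, y = ctr, charge = 0.5,
                               tail_angle = 0.8),
                          v0 = 10, decay_length = 500, cfg = cfg)
  rot <- rotate_frame(fp, c(ctr, ctr), 0.8, half_extent = 800)
  bx <- plus_half_boxes(rot)
  expect_lt(bx$mean_vx[bx$box == "right"], 0)
  expect_gt(bx$mean_vx[bx$box == "left"], 0)
})

test_that("minus-half sectors: A counterclockwise, B clockwise, outflow off-leg", {
  cfg <- scene_config(shape = c(1024L, 1024L), pixel_size = 2, seed = 1L)
  ctr <- 1023
  legs <- (2 / 3) * (0.5 + pi * 0:2)
  fm <- defect_flow_field(list(x = ctr, y = ctr, charge = -0.5,
                               leg_angles = legs),
                          v0 = 10, decay_length = 600, cfg = cfg)
  pol <- polar_components(fm, c(ctr, ctr))
  sec <- minus_half_sectors(pol, legs, r_min = 250, leg_halfwidth = 45,
                            r_max = 1000)
  expect_gt(sec$v_phi_A, 0)
  expect_lt(sec$v_phi_B, 0)
  expect_gt(sec$v_r_off_leg, 0)
  expect_equal(sec$v_r_on_leg, 0, tolerance = 1e-9)
  expect_false(sec$flagged)
  # sector magnitudes match direct integration of the template
  cm <- field_coords_for_test(fm)
  r <- sqrt((cm$x - ctr)^2 + (cm$y - ctr)^2)
  inside <- r > 250 & r <= 1000
  zones <- sec$zone
  phi <- atan2(cm$y - ctr, cm$x - ctr)
  vphi <- -fm$vx * sin(phi) + fm$vy * cos(phi)
  expect_equal(sec$v_phi_A, mean(vphi[zones == "A"]), tolerance = 1e-9)
  # partition: every node inside the annulus is in exactly one zone
  expect_true(all(zones[inside] %in% c("A", "B", "leg")))
  expect_true(all(zones[!inside] == "excluded"))
  expect_equal(sum(sec$n_A, sec$n_B, sec$n_on_leg), sum(inside))
})

test_that("zero field gives zero sector means", {
  g <- seq(0, 1000, by = 20)
  z <- velocity_field(matrix(0, length(g), length(g)),
                      matrix(0, length(g), length(g)), x = g, y = g)
  pol <- polar_components(z, c(500, 500))
  sec <- minus_half_sectors(pol, c(0.2, 0.2 + 2 * pi / 3, 0.2 + 4 * pi / 3),
                            r_min = 100, r_max = 480)
  expect_equal(sec$v_phi_A, 0)
  expect_equal(sec$v_phi_B, 0)
})

test_that("control boxes on isotropic flow average to zero, on drift to the drift", {
  g <- seq(0, 3000, by = 10)
  set.seed(42)
  iso <- velocity_field(matrix(stats::rnorm(length(g)^2, 0, 3), length(g)),
                        matrix(stats::rnorm(length(g)^2, 0, 3), length(g)),
                        x = g, y = g)
  ctl <- control_summary(iso, n_boxes = 21, seed = 7)
  grand <- mean(ctl$mean_vx)
  se <- stats::sd(ctl$mean_vx) / sqrt(nrow(ctl))
  expect_lt(abs(grand), 3 * se + 0.05)
  # uniform drift: every box mean equals the drift
  dr <- velocity_field(matrix(2, length(g), length(g)),
                       matrix(-1, length(g), length(g)), x = g, y = g)
  cd <- control_summary(dr, n_boxes = 5, seed = 3)
  expect_equal(unique(round(cd$mean_vx, 9)), 2)
  expect_equal(unique(round(cd$mean_vy, 9)), -1)
  # zero field: zeros
  z <- velocity_field(matrix(0, length(g), length(g)),
                      matrix(0, length(g), length(g)), x = g, y = g)
  cz <- control_summary(z, n_boxes = 3, seed = 1)
  expect_equal(unique(cz$mean_vx), 0)
  # too-small field errors
  small <- velocity_field(matrix(0, 5, 5), matrix(0, 5, 5),
                          x = seq(0, 40, 10), y = seq(0, 40, 10))
  expect_error(control_summary(small, 1), "too small")
})

test_that("plus-half box summary is invariant under a 90-degree scene rotation", {
  cfg <- scene_config(shape = c(1024L, 1024L), pixel_size = 2, seed = 1L)
  ctr <- 1023
  for (tail in c(0.3, 2.0)) {
    f1 <- defect_flow_field(list(x = ctr, y = ctr, charge = 0.5,
                                 tail_angle = tail),
                            v0 = 10, decay_length = 500, cfg = cfg)
    b1 <- plus_half_boxes(rotate_frame(f1, c(ctr, ctr), tail,
                                       half_extent = 800))
    f2 <- defect_flow_field(list(x = ctr, y = ctr, charge = 0.5,
                                 tail_angle = tail + pi / 2),
                            v0 = 10, decay_length = 500, cfg = cfg)
    b2 <- plus_half_boxes(rotate_frame(f2, c(ctr, ctr), tail + pi / 2,
                                       half_extent = 800))
    expect_equal(b1$mean_vx, b2$mean_vx, tolerance = 0.05)
  }
})
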