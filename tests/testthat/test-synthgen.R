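# Synthetic-scene generators: planted topology, determinism, and the
# statistical contracts of each scene type.

test_that("planted director fields carry the planted winding number", {
  for (q in c(0.5, -0.5)) {
    sc <- defect_scene(q, phase = 0.3)
    ctr_node <- round(dim(sc$field$theta) / 2)
    for (half in c(10L, 30L)) {
      lp <- square_loop(ctr_node[1], ctr_node[2], half)
      expect_equal(as.numeric(winding_number(sc$field, lp)), q)
    }
  }
})

test_that("winding around a dipole pair is zero, around each core its charge", {
  cfg <- scene_config(shape = c(256L, 256L), pixel_size = 1, seed = 2L)
  dp <- planted_defect(100, 128, 0.5, 0.2)
  dm <- planted_defect(156, 128, -0.5, 0.9)
  fld <- ideal_director_field(list(dp, dm), cfg)
  # loop enclosing both: numeric wrapped-difference sum is 0
  big <- square_loop(129L, 129L, 60L)
  expect_equal(as.numeric(winding_number(fld, big)), 0)
  expect_equal(as.numeric(winding_number(fld, square_loop(129L, 101L, 15L))), 0.5)
  expect_equal(as.numeric(winding_number(fld, square_loop(129L, 157L, 15L))), -0.5)
})

test_that("overlapping or out-of-grid defect cores are rejected", {
  cfg <- scene_config(shape = c(128L, 128L), pixel_size = 1, seed = 1L)
  expect_error(ideal_director_field(list(planted_defect(60, 60, 0.5),
                                         planted_defect(65, 60, -0.5)), cfg),
               "overlapping")
  expect_error(ideal_director_field(list(planted_defect(500, 60, 0.5)), cfg),
               "outside")
  expect_error(planted_defect(10, 10, charge = 1))
})

test_that("generators are bit-identical under a fixed seed", {
  cfg <- scene_config(shape = c(128L, 128L), seed = 11L, noise = 0.1)
  f1 <- ideal_director_field(list(planted_defect(40, 40, 0.5)), cfg)
  f2 <- ideal_director_field(list(planted_defect(40, 40, 0.5)), cfg)
  expect_identical(f1$theta, f2$theta)
  expect_identical(render_cell_texture(f1, 16, cfg),
                   render_cell_texture(f2, 16, cfg))
  n1 <- nuclei_image(300, 4, 1000, cfg)
  n2 <- nuclei_image(300, 4, 1000, cfg)
  expect_identical(n1$image, n2$image)
  s1 <- clearance_scene(1e4, 2500, 5, cfg)
  s2 <- clearance_scene(1e4, 2500, 5, cfg)
  expect_identical(s1$areas, s2$areas)
})

test_that("rendered texture is oriented along the planted director", {
  sc <- make_texture_scene(angle = pi / 6, noise = 0)
  est <- estimate_director(sc$tex, pixel_size = 0.625)
  inner <- est$theta[40:216, 40:216]
  err <- (inner - pi / 6 + pi / 2) %% pi - pi / 2
  expect_lt(sqrt(mean(err^2)) * 180 / pi, 5)
  # rotating the planted field rotates the measured orientation
  sc45 <- make_texture_scene(angle = pi / 6 + pi / 4, noise = 0)
  est45 <- estimate_director(sc45$tex, pixel_size = 0.625)
  d <- (est45$theta[40:216, 40:216] - inner - pi / 4 + pi / 2) %% pi - pi / 2
  expect_lt(abs(mean(d)) * 180 / pi, 2)
  # zero streak length injects no anisotropy
  cfg <- scene_config(shape = c(256L, 256L), seed = 5L)
  iso <- render_cell_texture(sc$field, 0.5, cfg)
  est_iso <- estimate_director(iso, pixel_size = 0.625)
  expect_lt(mean(est_iso$coherence[40:216, 40:216]), 0.1)
})

test_that("flow templates have the defect-driven sign structure", {
  cfg <- scene_config(shape = c(512L, 512L), pixel_size = 2, seed = 1L)
  ctr <- 511
  # +1/2, tail along +x: inward x-flow on both sides
  fp <- defect_flow_field(list(x = ctr, y = ctr, charge = 0.5, tail_angle = 0),
                          v0 = 10, decay_length = 300, cfg = cfg)
  cm <- list(x = matrix(fp$x, nrow(fp$vx), ncol(fp$vx), byrow = TRUE) - ctr,
             y = matrix(fp$y, nrow(fp$vx), ncol(fp$vx)) - ctr)
  expect_lt(mean(fp$vx[cm$x > 50]), 0)
  expect_gt(mean(fp$vx[cm$x < -50]), 0)
  expect_equal(max(abs(fp$vy)), 0)
  # v0 = 0 gives the zero field
  f0 <- defect_flow_field(list(x = ctr, y = ctr, charge = 0.5, tail_angle = 0),
                          v0 = 0, decay_length = 300, cfg = cfg)
  expect_equal(max(abs(f0$vx), abs(f0$vy)), 0)
  # unknown charge rejected
  expect_error(defect_flow_field(list(x = ctr, y = ctr, charge = 1),
                                 v0 = 1, decay_length = 100, cfg = cfg),
               "charge")
  # -1/2: angular flow converges on the legs, radial flow outward off-leg
  legs <- (2 / 3) * (0.3 + pi * 0:2)
  fm <- defect_flow_field(list(x = ctr, y = ctr, charge = -0.5,
                               leg_angles = legs),
                          v0 = 10, decay_length = 300, cfg = cfg)
  pol <- polar_components(fm, c(ctr, ctr))
  sec <- minus_half_sectors(pol, legs, r_min = 100, leg_halfwidth = 45,
                            r_max = 450)
  expect_gt(sec$v_phi_A, 0)
  expect_lt(sec$v_phi_B, 0)
  expect_gt(sec$v_r_off_leg, 0)
  expect_equal(sec$v_r_on_leg, 0, tolerance = 1e-9)
})

test_that("advect_image warps by the requested displacement", {
  sc <- make_texture_scene()
  expect_equal(advect_image(sc$tex, 0, 0), sc$tex, ignore_attr = TRUE)
  b <- advect_image(sc$tex, 3, 0)
  v <- piv_displacement(sc$tex, b)
  dx_px <- mean(v$vx[v$mask]) * (1 / 6) / 0.625
  expect_equal(dx_px, 3, tolerance = 0.2 / 3)
  expect_error(advect_image(sc$tex, 40, 0), "half the correlation subset")
})

test_that("nuclei are Poisson-placed with the requested density", {
  cfg0 <- scene_config(shape = c(500L, 500L), pixel_size = 2, seed = 1L)
  blank <- nuclei_image(0, 4, 1000, cfg0)
  expect_equal(sum(blank$image), 0)
  expect_equal(nrow(blank$positions), 0)
  expect_error(nuclei_image(function(x, y) -x, 4, 1000, cfg0), "non-negative")
  # 1 mm^2 at 500 cells/mm^2: mean count over seeds within 3 SE of 500
  counts <- vapply(1:20, function(s) {
    cfg <- scene_config(shape = c(500L, 500L), pixel_size = 2, seed = s)
    nrow(nuclei_image(500, 4, 1000, cfg)$positions)
  }, 0)
  se <- sqrt(500 / 20)
  expect_lt(abs(mean(counts) - 500), 3 * se)
  # total intensity ~ n_cells * intensity_per_cell (border clipping aside)
  cfg <- scene_config(shape = c(500L, 500L), pixel_size = 2, seed = 3L)
  ni <- nuclei_image(500, 4, 1000, cfg)
  expect_equal(sum(ni$image) / (nrow(ni$positions) * 1000), 1, tolerance = 0.03)
})

test_that("clearance scenes grow cleared area linearly at the planted rate", {
  cfg <- scene_config(shape = c(128L, 128L), pixel_size = 4, seed = 2L)
  scn <- clearance_scene(1e4, 2500, 15, cfg)
  fit <- clearance_rate(scn$areas$time_h, scn$areas$cleared_area)
  expect_equal(fit$rate, 2500)
  expect_equal(normalized_rate(fit$rate, scn$areas$spheroid_area[1]), 0.25)
  expect_equal(unique(scn$areas$spheroid_area), 1e4)
  scn0 <- clearance_scene(1e4, 0, 5, cfg)
  expect_equal(clearance_rate(scn0$areas$time_h, scn0$areas$cleared_area)$rate, 0)
})
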