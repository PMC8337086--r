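# Defect detection, charge measurement, axis estimation, and tracking.

test_that("winding number is a clean half-integer matching the oracle", {
  # 100 random smooth multi-defect fields: wrapped-difference winding
  # agrees with brute-force phase unwrapping on the same loop
  for (s in 1:100) {
    set.seed(s)
    cfg <- scene_config(shape = c(96L, 96L), pixel_size = 1, seed = s)
    n_def <- sample(0:2, 1)
    defs <- list()
    if (n_def >= 1) defs <- c(defs, list(planted_defect(
      stats::runif(1, 20, 35), stats::runif(1, 20, 75),
      sample(c(0.5, -0.5), 1), stats::runif(1, 0, pi))))
    if (n_def == 2) defs <- c(defs, list(planted_defect(
      stats::runif(1, 60, 75), stats::runif(1, 20, 75),
      sample(c(0.5, -0.5), 1), stats::runif(1, 0, pi))))
    fld <- ideal_director_field(defs, cfg)
    lp <- square_loop(48L, 48L, 40L)
    w <- as.numeric(winding_number(fld, lp))
    expect_equal(w, unwrap_winding(fld, lp), tolerance = 1e-9)
    expect_equal(w * 2, round(w * 2))
  }
})

test_that("winding requires a loop of at least 8 nodes", {
  f <- orientation_field(matrix(0.3, 16, 16))
  expect_error(winding_number(f, cbind(c(4, 4, 8, 8), c(4, 8, 8, 4))),
               "at least 8")
})

test_that("detection finds planted defects exactly, nothing elsewhere", {
  for (q in c(0.5, -0.5)) {
    scn <- defect_scene(q, phase = 0.7)
    d <- detect_defects(scn$field)
    expect_equal(nrow(d), 1L)
    expect_equal(d$charge, q)
    sp <- 0.625
    expect_lt(sqrt((d$x - scn$center[1])^2 + (d$y - scn$center[2])^2), sp)
    expect_identical(d$flag, "")
  }
  # defect-free uniform field
  u <- orientation_field(matrix(0.4, 128, 128))
  expect_equal(nrow(detect_defects(u)), 0L)
  # dipole pair 100 px apart: both found with correct charges
  cfg <- scene_config(shape = c(256L, 256L), pixel_size = 1, seed = 2L)
  fld <- ideal_director_field(list(planted_defect(78.5, 128.5, 0.5, 0.2),
                                   planted_defect(178.5, 128.5, -0.5, 0.9)), cfg)
  d2 <- detect_defects(fld)
  expect_equal(nrow(d2), 2L)
  expect_setequal(d2$charge, c(0.5, -0.5))
})

test_that("charge conservation and gauge invariance hold on random fields", {
  for (s in 1:10) {
    cfg <- scene_config(shape = c(160L, 160L), pixel_size = 1, seed = s,
                        noise = 0.05)
    fld <- ideal_director_field(list(planted_defect(50, 60, 0.5, 0.3),
                                     planted_defect(115, 100, -0.5, 1.2)), cfg)
    d <- detect_defects(fld)
    expect_true(all(d$charge %in% c(0.5, -0.5) | d$flag != ""))
    lp <- square_loop(80L, 80L, 70L)
    expect_equal(sum(d$charge), as.numeric(winding_number(fld, lp)))
    # adding pi to every angle changes nothing
    g <- fld
    g$theta <- (g$theta + pi) %% pi
    expect_equal(detect_defects(g), d)
  }
})

test_that("ring fit recovers planted charge and phase", {
  cases <- list(c(0.5, 0.3), c(-0.5, 1.0), c(0.5, 2.8))
  for (cs in cases) {
    scn <- defect_scene(cs[1], phase = cs[2])
    fit <- ring_phase_fit(scn$field, scn$center, radius = 10)
    expect_equal(fit$charge, cs[1], tolerance = 0.02)
    d0 <- (fit$theta0 - cs[2] + pi / 2) %% pi - pi / 2
    expect_lt(abs(d0), 0.05)
    expect_false(fit$poor_fit)
  }
  # uniform field: charge ~ 0
  u <- orientation_field(matrix(0.8, 64, 64))
  expect_lt(abs(ring_phase_fit(u, c(32, 32), radius = 10)$charge), 0.05)
  expect_error(ring_phase_fit(u, c(2, 2), radius = 10), "outside")
})

test_that("defect axes have the charge-specific symmetry", {
  # -1/2, theta0 = 0: legs at 0, 120, 240 degrees
  scn <- defect_scene(-0.5, phase = 0)
  d <- detect_defects(scn$field)
  legs <- defect_axes(scn$field, d[1, ])
  expect_length(legs, 3L)
  expect_equal(sort(legs) * 180 / pi, c(0, 120, 240), tolerance = 0.5)
  # +1/2: exactly one axis; ideal tail at 2*theta0 + pi
  scp <- defect_scene(0.5, phase = 0.3)
  dp <- detect_defects(scp$field)
  tail <- defect_axes(scp$field, dp[1, ])
  expect_length(tail, 1L)
  expect_equal(as.numeric(tail), 2 * 0.3 + pi, tolerance = 0.02)
  # rotating the whole field by alpha rotates all axes by alpha:
  # a -1/2 with phase theta0 + (3/2) alpha ... use the axis equation via
  # two different phases as an equivariance probe
  scn2 <- defect_scene(-0.5, phase = 0.6)
  d2 <- detect_defects(scn2$field)
  legs2 <- defect_axes(scn2$field, d2[1, ])
  # axes phi_k = (2/3)(theta0 + k pi): phase 0 -> 0.6 shifts axes by 0.4
  expect_equal(sort((legs2 - 0.4) %% (2 * pi)) * 180 / pi, c(0, 120, 240),
               tolerance = 0.5)
})

test_that("adjacent -1/2 axes are separated by 120 degrees across phases", {
  for (ph in c(0.3, 1.0, 2.0)) {
    scn <- defect_scene(-0.5, phase = ph, shape = c(192L, 192L))
    d <- detect_defects(scn$field)
    legs <- sort(defect_axes(scn$field, d[1, ]))
    seps <- diff(c(legs, legs[1] + 2 * pi)) * 180 / pi
    expect_equal(seps, rep(120, 3), tolerance = 0.5)
  }
})

test_that("tracking links by nearest neighbour with a distance cap", {
  # stationary defect over 10 frames: one track, zero speed
  stat <- do.call(rbind, lapply(1:10, function(f)
    data.frame(frame = f, x = 50, y = 50, charge = 0.5)))
  tr <- track_defects(stat, max_link = 10, frame_interval = 1)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$mean_speed, 0)
  expect_equal(tr$n_frames, 10L)
  # defect moving 1 um per 1 h frame: speed 1 um/h
  mov <- do.call(rbind, lapply(1:10, function(f)
    data.frame(frame = f, x = 50 + (f - 1), y = 50, charge = 0.5)))
  tr2 <- track_defects(mov, max_link = 5, frame_interval = 1)
  expect_equal(nrow(tr2), 1L)
  expect_equal(tr2$mean_speed, 1)
  expect_equal(tr2$net_displacement, 9)
  expect_lte(tr2$net_displacement, tr2$path_length)
  # jump beyond max_link terminates the track instead of linking
  jump <- rbind(data.frame(frame = 1, x = 0, y = 0, charge = 0.5),
                data.frame(frame = 2, x = 100, y = 0, charge = 0.5))
  tr3 <- track_defects(jump, max_link = 20)
  expect_equal(nrow(tr3), 2L)
  # opposite charges never link even when close
  mixed <- rbind(data.frame(frame = 1, x = 0, y = 0, charge = 0.5),
                 data.frame(frame = 2, x = 1, y = 0, charge = -0.5))
  expect_equal(nrow(track_defects(mixed, max_link = 20)), 2L)
})

test_that("tracking a drifting planted defect recovers its speed", {
  # 1 um/frame drift at 1 h intervals, detected per frame from the field
  recs <- do.call(rbind, lapply(0:5, function(k) {
    cfg <- scene_config(shape = c(128L, 128L), pixel_size = 1, seed = 1L)
    fld <- ideal_director_field(list(planted_defect(50 + k, 64, 0.5, 0.3)), cfg)
    d <- detect_defects(fld)
    d$frame <- k + 1L
    d
  }))
  tr <- track_defects(recs, max_link = 5, frame_interval = 1)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$mean_speed, 1, tolerance = 0.3)  # grid quantization
})
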