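# Shared fixtures: all synthetic, built in code at test time.

# intensity bands oriented along `angle` (director should equal `angle`)
stripes_image <- function(angle, shape = c(128L, 128L), wavelength = 16) {
  x <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  y <- matrix(seq_len(shape[1]), shape[1], shape[2])
  u <- -x * sin(angle) + y * cos(angle)   # coordinate normal to the bands
  sin(2 * pi * u / wavelength)
}

# rendered cell texture with a uniform director plus angular jitter
make_texture_scene <- function(angle = pi / 6, noise = 0.15, seed = 5L,
                               shape = c(256L, 256L), streak = 16) {
  cfg <- scene_config(shape = shape, seed = seed)
  fld <- ideal_director_field(list(), cfg)
  if (noise > 0) {
    set.seed(seed + 1000L)
    jitter <- matrix(stats::rnorm(prod(shape), 0, noise), shape[1], shape[2])
  } else jitter <- 0
  fld$theta <- (fld$theta + angle + jitter) %% pi
  list(field = fld, tex = render_cell_texture(fld, streak, cfg), cfg = cfg)
}

# one planted defect centred in a square scene
defect_scene <- function(charge, phase = 0.3, shape = c(256L, 256L),
                         pixel_size = 0.625, seed = 3L, noise = 0) {
  cfg <- scene_config(shape = shape, pixel_size = pixel_size, seed = seed,
                      noise = noise)
  ctr <- (shape - 1) * pixel_size / 2
  pd <- planted_defect(ctr[2], ctr[1], charge, phase)
  list(field = ideal_director_field(list(pd), cfg), defect = pd, cfg = cfg,
       center = c(ctr[2], ctr[1]))
}

# independent winding oracle: brute-force phase unwrapping along the loop,
# choosing at each step the representative theta + m*pi (m enumerated)
# closest to the running value
unwrap_winding <- function(field, loop) {
  th <- field$theta[loop]
  cur <- th[1]
  path <- cur
  for (k in c(seq_along(th)[-1], 1L)) {
    cand <- th[k] + pi * (-3:3)
    cur <- cand[which.min(abs(cand - cur))]
    path <- c(path, cur)
  }
  (path[length(path)] - path[1]) / (2 * pi)
}

# square loop of grid nodes around (row0, col0)
square_loop <- function(row0, col0, half) {
  r <- (row0 - half):(row0 + half)
  c <- (col0 - half):(col0 + half)
  rbind(cbind(min(r), c), cbind(r[-1], max(c)),
        cbind(max(r), rev(c)[-1]), cbind(rev(r)[-1], min(c)))
}

# coordinate matrices for a velocity field (test-local copy)
field_coords_for_test <- function(field) {
  nr <- length(field$y); nc <- length(field$x)
  list(x = matrix(field$x, nr, nc, byrow = TRUE), y = matrix(field$y, nr, nc))
}

# exact two-sided rank-sum p by full enumeration of group assignments
enumerate_rank_sum_p <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n1)])
  sets <- utils::combn(n, n1)
  ws <- apply(sets, 2, function(ix) sum(r[ix]))
  lo <- mean(ws <= w_obs); hi <- mean(ws >= w_obs)
  min(1, 2 * min(lo, hi))
}
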