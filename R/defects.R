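# Detection, classification, orientation, and tracking of half-integer
# topological defects in a director field.
#
# A defect is a point where the director is discontinuous; its charge is
# the total director rotation around an enclosing loop divided by 2*pi.
# Because theta ~ theta + pi, charges come in multiples of 1/2. The +1/2
# ("comet") defect has one symmetry axis, the -1/2 ("trefoil") defect has
# three legs separated by 120 degrees.

#' Winding number of a director field along a closed loop
#'
#' Sums successive director differences wrapped into (-pi/2, pi/2] along
#' the loop and divides by 2*pi. The sum of wrapped differences around a
#' closed loop is a multiple of pi by construction, so the result is an
#' exact multiple of 1/2 (rounded at tolerance 1e-6).
#'
#' @param field an [orientation_field()]
#' @param loop integer matrix with columns `row`, `col`: ordered nodes of
#'   a closed simple loop (first node need not be repeated); >= 8 nodes
#' @param coherence_floor nodes below this coherence make the result
#'   unreliable (attribute `"reliable"` set to FALSE)
#' @return half-integer winding number, attribute `reliable`
#' @export
winding_number <- function(field, loop, coherence_floor = 0) {
  loop <- as.matrix(loop)
  if (nrow(loop) < 8) stop("loop must have at least 8 nodes")
  th <- field$theta[loop]
  d <- wrap_nematic_diff(diff(c(th, th[1])))
  w <- sum(d) / (2 * pi)
  q <- round(2 * w) / 2
  if (abs(q - w) > 1e-6)
    warning("winding number not a clean half-integer; noisy loop?")
  reliable <- all(field$coherence[loop] >= coherence_floor)
  structure(q, reliable = reliable)
}

# circle of grid nodes around (row0, col0); radius in nodes
loop_nodes <- function(field, row0, col0, radius, n = max(16L, 8L * radius)) {
  ang <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  rr <- round(row0 + radius * sin(ang))
  cc <- round(col0 + radius * cos(ang))
  keep <- !duplicated(cbind(rr, cc))
  cbind(row = rr[keep], col = cc[keep])
}

#' Detect half-integer defects in a director field
#'
#' Every 2x2 plaquette with nonzero winding becomes a candidate;
#' candidates within `merge_radius` are clustered (single linkage) and
#' each cluster's centroid is confirmed by re-measuring the winding on a
#' circle of `loop_radius` nodes. Records are sorted row-major by
#' position for determinism.
#'
#' @param field an [orientation_field()]
#' @param coherence_max only consider plaquettes whose minimum coherence
#'   is at or below this value (defect cores have depressed coherence in
#'   measured fields); default 1 disables the gate
#' @param loop_radius confirmation-ring radius in grid nodes
#' @param merge_radius cluster radius in micrometres (default 3 nodes)
#' @return data.frame with columns `x`, `y` (um), `charge`, `phase`,
#'   `core_coherence`, `flag` ("" | "unresolved")
#' @export
detect_defects <- function(field, coherence_max = 1, loop_radius = 5L,
                           merge_radius = NULL) {
  sp <- field_spacing(field)
  if (is.null(merge_radius)) merge_radius <- 3 * sp
  th <- field$theta
  nr <- nrow(th); nc <- ncol(th)
  # plaquette winding, vectorized over all 2x2 cells
  d1 <- wrap_nematic_diff(th[-nr, -1] - th[-nr, -nc])   # (i,j) -> (i,j+1)
  d2 <- wrap_nematic_diff(th[-1, -1] - th[-nr, -1])     # -> (i+1,j+1)
  d3 <- wrap_nematic_diff(th[-1, -nc] - th[-1, -1])     # -> (i+1,j)
  d4 <- wrap_nematic_diff(th[-nr, -nc] - th[-1, -nc])   # -> (i,j)
  w <- (d1 + d2 + d3 + d4) / (2 * pi)
  cand <- which(abs(w) > 0.25, arr.ind = TRUE)
  empty <- data.frame(x = numeric(0), y = numeric(0), charge = numeric(0),
                      phase = numeric(0), core_coherence = numeric(0),
                      flag = character(0), stringsAsFactors = FALSE)
  if (nrow(cand) == 0) return(empty)
  if (coherence_max < 1) {
    cmin <- pmin(field$coherence[-nr, -nc], field$coherence[-nr, -1],
                 field$coherence[-1, -nc], field$coherence[-1, -1])
    cand <- cand[cmin[cand] <= coherence_max, , drop = FALSE]
    if (nrow(cand) == 0) return(empty)
  }
  # candidate centers in node units (plaquette center)
  pr <- cand[, 1] + 0.5; pc <- cand[, 2] + 0.5
  qs <- w[cand]
  # single-linkage clustering within merge_radius
  n <- length(pr)
  cl <- seq_len(n)
  lim2 <- (merge_radius / sp)^2
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      d2i <- (pr - pr[i])^2 + (pc - pc[i])^2
      nb <- d2i <= lim2
      newcl <- min(cl[nb])
      if (any(cl[nb] != newcl)) { cl[nb] <- newcl; changed <- TRUE }
    }
    if (!changed) break
  }
  recs <- lapply(unique(cl), function(g) {
    sel <- cl == g
    r0 <- mean(pr[sel]); c0 <- mean(pc[sel])
    radius <- min(loop_radius, r0 - 1, c0 - 1, nr - r0, nc - c0)
    flag <- ""
    if (radius >= 2) {
      lp <- loop_nodes(field, r0, c0, radius)
      q <- as.numeric(winding_number(field, lp))
    } else {
      q <- round(2 * sum(qs[sel])) / 2
      flag <- "unresolved"
    }
    if (!q %in% c(0.5, -0.5)) flag <- "unresolved"
    core <- field$coherence[round(r0), round(c0)]
    data.frame(x = field$x[1] + (c0 - 1) * sp, y = field$y[1] + (r0 - 1) * sp,
               charge = q, phase = NA_real_, core_coherence = core,
               flag = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  # flag pairs closer than 2 * loop_radius (rings overlap)
  if (nrow(out) > 1) {
    dd <- as.matrix(stats::dist(out[, c("x", "y")]))
    diag(dd) <- Inf
    near <- apply(dd, 1, min) < 2 * loop_radius * sp
    out$flag[near & out$flag == ""] <- "unresolved neighborhood"
  }
  out <- out[order(out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  # fill phase from the ring fit where the charge is clean
  for (i in seq_len(nrow(out))) {
    if (out$charge[i] %in% c(0.5, -0.5)) {
      fit <- try(ring_phase_fit(field, c(out$x[i], out$y[i]),
                                radius = loop_radius * sp), silent = TRUE)
      if (!inherits(fit, "try-error")) out$phase[i] <- fit$theta0
    }
  }
  out
}

#' Least-squares charge and phase on a ring
#'
#' Samples the director on a circle around `center`, unwraps the doubled
#' angle 2*theta along the ring (respecting nematic symmetry), and fits
#' 2*theta = 2*q*phi + 2*theta0 by ordinary least squares.
#'
#' @param field an [orientation_field()]
#' @param center `c(x, y)` in micrometres
#' @param radius ring radius in micrometres; ring must lie inside the field
#' @param n_samples points on the ring
#' @return list `charge` (slope / 2), `theta0` in \[0, pi),
#'   `residual` (circular RMS of the fit, radians), `poor_fit` flag
#' @export
ring_phase_fit <- function(field, center, radius, n_samples = 90L) {
  sp <- field_spacing(field)
  if (center[1] - radius < min(field$x) || center[1] + radius > max(field$x) ||
      center[2] - radius < min(field$y) || center[2] + radius > max(field$y))
    stop("ring extends outside the field")
  phi <- seq(0, 2 * pi, length.out = n_samples + 1L)[-(n_samples + 1L)]
  s <- sample_director(field, center[1] + radius * cos(phi),
                       center[2] + radius * sin(phi))
  th2 <- 2 * s$theta
  # unwrap the doubled angle along the ring
  d <- wrap_angle(diff(th2))
  u <- c(th2[1], th2[1] + cumsum(d))
  fit <- stats::lm.fit(cbind(1, phi), u)
  q <- fit$coefficients[2] / 2
  theta0 <- wrap_nematic(fit$coefficients[1] / 2)
  resid_circ <- sqrt(mean(wrap_angle(fit$residuals)^2)) / 2
  list(charge = unname(q), theta0 = unname(theta0),
       residual = resid_circ, poor_fit = resid_circ > 0.35)
}

#' Symmetry axes of a half-integer defect
#'
#' An axis is a direction phi along which the director is radial, i.e.
#' (1 - q) * phi = theta0 (mod pi). Rather than placing axes from the
#' fitted phase alone, each axis is located independently by root-finding
#' the radial-director residual g(phi) = theta(phi) - phi (wrapped mod
#' pi) on a ring around the core. A -1/2 defect yields three legs
#' (analytically 120 degrees apart); a +1/2 defect yields the single
#' comet-tail axis, whose *sign* is set by the defect polarization
#' p = (dx Qxx + dy Qxy, dx Qxy - dy Qyy) of the coherence-weighted
#' nematic tensor: the tail points along -p (the side where the director
#' bends around the core).
#'
#' @param field an [orientation_field()]
#' @param record one row of [detect_defects()] output (list or data.frame
#'   row with `x`, `y`, `charge`)
#' @param radius evaluation-ring radius (um); default 5 grid nodes
#' @param coherence_floor below this mean ring coherence the axes are
#'   flagged low-confidence
#' @return numeric vector of axis angles in \[0, 2*pi) (length 1 for
#'   +1/2, 3 for -1/2), attribute `low_confidence`
#' @export
defect_axes <- function(field, record, radius = NULL,
                        coherence_floor = 0.05) {
  sp <- field_spacing(field)
  if (is.null(radius)) radius <- 5 * sp
  q <- record$charge
  if (!q %in% c(0.5, -0.5)) stop("defect_axes needs charge +1/2 or -1/2")
  n <- 720L
  phi <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  s <- sample_director(field, record$x + radius * cos(phi),
                       record$y + radius * sin(phi))
  low_conf <- mean(s$coherence, na.rm = TRUE) < coherence_floor
  g <- wrap_nematic_diff(s$theta - phi)    # 0 where the director is radial
  if (q < 0) {
    axes <- find_radial_roots(phi, g, expected = 3L)
  } else {
    # a +1/2 defect has a single radial direction; the root fixes the
    # axis line and the polarization fixes which end is the tail
    roots <- find_radial_roots(phi, g, expected = 1L)
    p <- defect_polarization(field, record)
    tail_ref <- atan2(-p[2], -p[1]) %% (2 * pi)
    if (length(roots) == 1) {
      ends <- c((roots + pi) %% (2 * pi), roots)
      axes <- ends[which.min(abs(wrap_angle(ends - tail_ref)))]
    } else axes <- tail_ref
  }
  structure(axes, low_confidence = low_conf)
}

# roots of the wrapped residual g(phi) on a sampled ring: sign changes of
# g with small |g| on both sides, refined by linear interpolation
find_radial_roots <- function(phi, g, expected) {
  n <- length(phi)
  g2 <- c(g, g[1]); p2 <- c(phi, phi[1] + 2 * pi)
  roots <- numeric(0); depth <- numeric(0)
  for (i in seq_len(n)) {
    a <- g2[i]; b <- g2[i + 1]
    if (is.na(a) || is.na(b)) next
    if (abs(a) < pi / 4 && abs(b) < pi / 4 && a * b <= 0 && (a != 0 || b != 0)) {
      t <- if (a == b) 0.5 else a / (a - b)
      roots <- c(roots, p2[i] + t * (p2[i + 1] - p2[i]))
      depth <- c(depth, abs(a) + abs(b))
    }
  }
  roots <- roots %% (2 * pi)
  # merge duplicates straddling the 0 / 2*pi wrap (or adjacent samples)
  if (length(roots) > 1) {
    o <- order(roots)
    roots <- roots[o]; depth <- depth[o]
    gap <- 4 * pi / length(phi)
    keep <- rep(TRUE, length(roots))
    for (i in seq_along(roots)[-1]) {
      if (roots[i] - roots[i - 1] < gap) {
        if (depth[i] < depth[i - 1]) keep[i - 1] <- FALSE else keep[i] <- FALSE
      }
    }
    n_r <- length(roots)
    if (keep[1] && keep[n_r] && n_r > 1 && (roots[n_r] - roots[1]) > 2 * pi - gap)
      keep[if (depth[1] <= depth[n_r]) n_r else 1L] <- FALSE
    roots <- roots[keep]; depth <- depth[keep]
  }
  if (length(roots) > expected) roots <- roots[order(depth)][seq_len(expected)]
  sort(roots)
}

# polarization vector of a +1/2 defect from tensor divergence at the core
defect_polarization <- function(field, record, halo = 3L) {
  sp <- field_spacing(field)
  w <- field$coherence
  Qxx <- w * cos(2 * field$theta)
  Qxy <- w * sin(2 * field$theta)
  r0 <- round((record$y - field$y[1]) / sp) + 1L
  c0 <- round((record$x - field$x[1]) / sp) + 1L
  nr <- nrow(Qxx); nc <- ncol(Qxx)
  ri <- max(2L, r0 - halo):min(nr - 1L, r0 + halo)
  ci <- max(2L, c0 - halo):min(nc - 1L, c0 + halo)
  dxQxx <- (Qxx[ri, ci + 1L] - Qxx[ri, ci - 1L]) / (2 * sp)
  dyQxx <- (Qxx[ri + 1L, ci] - Qxx[ri - 1L, ci]) / (2 * sp)
  dxQxy <- (Qxy[ri, ci + 1L] - Qxy[ri, ci - 1L]) / (2 * sp)
  dyQxy <- (Qxy[ri + 1L, ci] - Qxy[ri - 1L, ci]) / (2 * sp)
  # traceless symmetric Q: Qyy = -Qxx
  c(mean(dxQxx + dyQxy), mean(dxQxy - (-dyQxx)))
}

#' Link per-frame defect records into tracks
#'
#' Greedy nearest-neighbour, same-charge linking frame to frame with a
#' hard distance cap; unmatched defects start or terminate tracks. Ties
#' are broken by smallest distance, then row-major record order, so the
#' result is deterministic.
#'
#' @param records data.frame of detections with a `frame` column plus the
#'   [detect_defects()] columns; frames must be consecutive integers
#' @param max_link maximum link distance (um) between consecutive frames
#' @param frame_interval hours per frame, for speeds
#' @return data.frame, one row per track: `track`, `charge`, `n_frames`,
#'   `path_length` (um), `net_displacement` (um), `mean_speed` (um/h);
#'   the per-frame positions are attached as attribute `"points"`
#' @export
track_defects <- function(records, max_link, frame_interval = 1) {
  stopifnot(nrow(records) > 0, "frame" %in% names(records))
  records <- records[order(records$frame, records$y, records$x), , drop = FALSE]
  records$track <- NA_integer_
  frames <- sort(unique(records$frame))
  next_id <- 1L
  prev_idx <- which(records$frame == frames[1])
  records$track[prev_idx] <- seq_along(prev_idx)
  next_id <- length(prev_idx) + 1L
  for (f in frames[-1]) {
    cur_idx <- which(records$frame == f)
    avail <- prev_idx
    # candidate links sorted by distance (then record order for ties)
    if (length(cur_idx) > 0 && length(avail) > 0) {
      cand <- expand.grid(i = cur_idx, j = avail)
      cand$d <- sqrt((records$x[cand$i] - records$x[cand$j])^2 +
                       (records$y[cand$i] - records$y[cand$j])^2)
      cand <- cand[records$charge[cand$i] == records$charge[cand$j] &
                     cand$d <= max_link, , drop = FALSE]
      cand <- cand[order(cand$d, cand$i, cand$j), , drop = FALSE]
      used_i <- integer(0); used_j <- integer(0)
      for (k in seq_len(nrow(cand))) {
        i <- cand$i[k]; j <- cand$j[k]
        if (i %in% used_i || j %in% used_j) next
        records$track[i] <- records$track[j]
        used_i <- c(used_i, i); used_j <- c(used_j, j)
      }
    }
    new <- cur_idx[is.na(records$track[cur_idx])]
    if (length(new) > 0) {
      records$track[new] <- seq.int(next_id, length.out = length(new))
      next_id <- next_id + length(new)
    }
    prev_idx <- cur_idx
  }
  tracks <- lapply(split(seq_len(nrow(records)), records$track), function(ix) {
    r <- records[ix, , drop = FALSE]
    r <- r[order(r$frame), , drop = FALSE]
    steps <- sqrt(diff(r$x)^2 + diff(r$y)^2)
    path <- sum(steps)
    net <- sqrt((r$x[nrow(r)] - r$x[1])^2 + (r$y[nrow(r)] - r$y[1])^2)
    elapsed <- (r$frame[nrow(r)] - r$frame[1]) * frame_interval
    data.frame(track = r$track[1], charge = r$charge[1], n_frames = nrow(r),
               path_length = path, net_displacement = net,
               mean_speed = if (elapsed > 0) path / elapsed else 0)
  })
  out <- do.call(rbind, tracks)
  out <- out[order(out$track), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "points") <- records
  out
}
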