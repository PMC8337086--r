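# End-to-end studies over synthetic scenes: velocity, density, and
# clearance. Each run takes a run_config, wires the modules together,
# writes CSV tables plus a JSON manifest, and is bit-reproducible from
# (config, seed).

#' Run configuration
#'
#' Collects every tunable parameter with the standard defaults: 64 px
#' correlation subsets on a 16 px grid, 500 x 750 um boxes 50 um apart,
#' a 250 um central exclusion, 45 um leg bands, 1800 um outer radius,
#' density circles from 10 to 350 um, and a 750 um defect-qualification
#' radius. Unknown keys are rejected.
#'
#' @param ... overrides of the defaults listed above
#' @return a `run_config` list
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1L,
    pixel_size = 0.625,         # um/px
    frame_interval = 1 / 6,     # h, 10-min imaging
    subset_px = 64L,
    spacing_px = 16L,
    box_w = 500, box_h = 750, gap = 50,            # um
    r_min = 250, leg_halfwidth = 45, r_max = 1800, # um
    radii = seq(10, 350, by = 20),                 # um
    qualification_radius = 750,                    # um
    clearance_frames = 15L, clearance_dt = 1,      # hourly for 15 h
    n_controls = 21L,
    v0 = 10, decay_length = 500,                   # synthetic flow
    out_dir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0)
    stop("unknown run_config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  class(cfg) <- "run_config"
  cfg
}

write_manifest <- function(cfg, path, extra = list()) {
  m <- c(list(package = "nemaclear",
              version = as.character(utils::packageVersion("nemaclear"))),
         unclass(cfg)[setdiff(names(unclass(cfg)), "out_dir")], extra)
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

write_table <- function(df, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(df, file.path(dir, name), row.names = FALSE)
}

#' Synthetic velocity study around a planted defect
#'
#' Generates a director scene with one planted defect, derives the flow
#' template, runs the defect-frame analysis (+1/2 boxes or -1/2
#' sectors), collects control boxes from a seeded defect-free flow, and
#' compares defect box means against controls.
#'
#' @param cfg a [run_config()]; `cfg$v0` and `cfg$decay_length` set the
#'   planted flow
#' @param charge +0.5 or -0.5, the planted defect
#' @param scene_px scene size in pixels (square)
#' @return list with `defects` (detection table), `summary`
#'   (boxes or sectors), `controls`, `tests`, `truth`
#' @export
run_velocity_study <- function(cfg = run_config(), charge = 0.5,
                               scene_px = 1024L) {
  sc <- scene_config(shape = c(scene_px, scene_px),
                     pixel_size = cfg$pixel_size, seed = cfg$seed,
                     frame_interval = cfg$frame_interval)
  extent <- (scene_px - 1) * cfg$pixel_size
  ctr <- extent / 2
  theta0 <- 0.3
  pd <- planted_defect(ctr, ctr, charge, phase = theta0)
  fld <- ideal_director_field(list(pd), sc)
  ds <- downsample_field(fld, 4L)
  dets <- detect_defects(ds)
  flow <- defect_flow_field(pd, v0 = cfg$v0, decay_length = cfg$decay_length,
                            cfg = sc, spacing_px = cfg$spacing_px)
  truth <- list(defect = pd, v0 = cfg$v0, decay_length = cfg$decay_length)
  # control flow: seeded isotropic noise velocities on the same grid
  set.seed(child_seed(cfg$seed, 7L))
  ctrl_flow <- velocity_field(
    matrix(stats::rnorm(length(flow$vx), 0, cfg$v0 / 4), nrow(flow$vx)),
    matrix(stats::rnorm(length(flow$vx), 0, cfg$v0 / 4), nrow(flow$vx)),
    x = flow$x, y = flow$y, frame_interval = flow$frame_interval)
  sum_box_w <- min(cfg$box_w, extent / 2 - cfg$gap)
  sum_box_h <- min(cfg$box_h, extent - 20)
  ctl_w <- min(sum_box_w, (extent - 2 * cfg$gap) / 4)
  controls <- control_summary(ctrl_flow, cfg$n_controls,
                              seed = child_seed(cfg$seed, 8L),
                              box_w = ctl_w, box_h = min(sum_box_h, extent / 2),
                              gap = cfg$gap)
  tests <- NULL
  if (charge > 0) {
    det <- dets[which.min((dets$x - ctr)^2 + (dets$y - ctr)^2), ]
    tail <- defect_axes(ds, det)
    rot <- rotate_frame(flow, c(det$x, det$y), tail[1])
    summary <- plus_half_boxes(rot, box_w = sum_box_w, box_h = sum_box_h,
                               gap = cfg$gap)
    # defect vs control: where does the defect's right-box mean fall in
    # the distribution of control box means? (one scene = one defect,
    # so this is a z-score, not a two-sample test)
    ctrl_right <- controls$mean_vx[controls$box == "right"]
    right_vx <- summary$mean_vx[summary$box == "right"]
    z <- (right_vx - mean(ctrl_right)) / stats::sd(ctrl_right)
    tests <- list(right_box_z = z,
                  right_box_p = 2 * stats::pnorm(-abs(z)))
    summary$tail_angle <- tail[1]
  } else {
    det <- dets[which.min((dets$x - ctr)^2 + (dets$y - ctr)^2), ]
    legs <- defect_axes(ds, det)
    pol <- polar_components(flow, c(det$x, det$y))
    summary <- minus_half_sectors(pol, legs, r_min = cfg$r_min,
                                  leg_halfwidth = cfg$leg_halfwidth,
                                  r_max = min(cfg$r_max, extent / 2))
    summary$legs <- legs
  }
  out <- list(defects = dets, summary = summary, controls = controls,
              tests = tests, truth = truth)
  if (!is.null(cfg$out_dir)) {
    write_table(dets, cfg$out_dir, "defects.csv")
    if (charge > 0) write_table(summary, cfg$out_dir, "velocity_summary.csv")
    else write_table(data.frame(group = c("A", "B", "on_leg", "off_leg"),
                                mean = c(summary$v_phi_A, summary$v_phi_B,
                                         summary$v_r_on_leg,
                                         summary$v_r_off_leg),
                                n = c(summary$n_A, summary$n_B,
                                      summary$n_on_leg, summary$n_off_leg)),
                     cfg$out_dir, "velocity_summary.csv")
    write_table(controls, cfg$out_dir, "velocity_controls.csv")
    write_manifest(cfg, file.path(cfg$out_dir, "manifest.json"),
                   list(study = "velocity", charge = charge,
                        scene_px = scene_px))
  }
  out
}

#' Synthetic density study at two timepoints
#'
#' Plants a radial density gradient around a defect position (stronger
#' at the later timepoint, emulating accumulation at a +1/2 core),
#' generates nuclei images, and runs the circle-profile analysis at both
#' timepoints, comparing the smallest-R densities by rank-sum across
#' replicate scenes.
#'
#' @param cfg a [run_config()]
#' @param base_density background density (cells/mm^2)
#' @param gradient_t0,gradient_t1 density slopes (cells/mm^2 per um of
#'   radius; negative = denser at the core) at the two timepoints
#' @param n_replicates replicate scenes per timepoint
#' @param scene_px scene size (pixels); pixel size fixed at 1 um here so
#'   the 350 um circle fits comfortably
#' @return list with `profiles`, `slopes`, `comparison`
#' @export
run_density_study <- function(cfg = run_config(), base_density = 1500,
                              gradient_t0 = 0, gradient_t1 = -6,
                              n_replicates = 6L, scene_px = 800L) {
  ps <- 1
  ctr <- (scene_px - 1) * ps / 2
  rmax_grad <- 400
  make_fn <- function(grad) function(x, y) {
    r <- pmin(sqrt((x - ctr)^2 + (y - ctr)^2), rmax_grad)
    pmax(base_density + grad * (r - rmax_grad / 2), 0)
  }
  one_tp <- function(grad, label, stream) {
    lapply(seq_len(n_replicates), function(i) {
      sci <- scene_config(shape = c(scene_px, scene_px), pixel_size = ps,
                          seed = child_seed(cfg$seed, stream * 100L + i))
      nim <- nuclei_image(make_fn(grad), spot_sigma = 4,
                          intensity_per_cell = 1000, cfg = sci)
      prof <- density_vs_radius(nim$image, c(ctr, ctr), radii = cfg$radii,
                                cell_intensity = 1000, pixel_size = ps,
                                timepoint = label)
      prof$replicate <- i
      prof
    })
  }
  p0 <- one_tp(gradient_t0, "t0", 1L)
  p1 <- one_tp(gradient_t1, "t1", 2L)
  mean_profile <- function(ps_list, label) {
    dens <- rowMeans(sapply(ps_list, function(p) p$density_cells_mm2))
    data.frame(radius_um = ps_list[[1]]$radius_um, count_est = NA,
               density_cells_mm2 = dens, timepoint = label)
  }
  m0 <- mean_profile(p0, "t0"); m1 <- mean_profile(p1, "t1")
  s0 <- density_slope(m0); s1 <- density_slope(m1)
  small0 <- vapply(p0, function(p) p$density_cells_mm2[1], 0)
  small1 <- vapply(p1, function(p) p$density_cells_mm2[1], 0)
  comparison <- compare_timepoints(small0, small1)
  profiles <- do.call(rbind, c(p0, p1))
  out <- list(profiles = profiles,
              slopes = data.frame(timepoint = c("t0", "t1"),
                                  slope = c(s0$slope, s1$slope),
                                  ci_lo = c(s0$ci[1], s1$ci[1]),
                                  ci_hi = c(s0$ci[2], s1$ci[2]),
                                  unit = s0$unit),
              comparison = comparison)
  if (!is.null(cfg$out_dir)) {
    write_table(profiles, cfg$out_dir, "density_profiles.csv")
    write_table(out$slopes, cfg$out_dir, "density_slopes.csv")
    write_manifest(cfg, file.path(cfg$out_dir, "manifest.json"),
                   list(study = "density", base_density = base_density,
                        gradient_t0 = gradient_t0, gradient_t1 = gradient_t1,
                        n_replicates = n_replicates, scene_px = scene_px))
  }
  out
}

#' Synthetic clearance study across location classes
#'
#' Simulates cohorts of clearance scenes whose planted rates are
#' suppressed on defects (factor `suppression` at +1/2 cores and -1/2
#' legs, none outside the legs), measures each trace from the rendered
#' masks, and compares classes.
#'
#' @param cfg a [run_config()]
#' @param n_per_class spheroids per location class
#' @param base_norm_rate control normalized clearance rate (h^-1)
#' @param suppression factor by which on-defect rates are reduced
#' @param area0 spheroid area (um^2)
#' @param scene_px,scene_pixel_size clearance scene raster
#' @param rate_cv lognormal coefficient of variation across spheroids
#' @param from_masks measure areas from rendered masks (TRUE) or from
#'   the scene's analytic area tables (FALSE, much faster)
#' @return list with `traces` (table) and `groups` (from [group_rates()])
#' @export
run_clearance_study <- function(cfg = run_config(), n_per_class = 10L,
                                base_norm_rate = 0.25, suppression = 2,
                                area0 = 1e4, scene_px = 256L,
                                scene_pixel_size = 3, rate_cv = 0.3,
                                from_masks = FALSE) {
  classes <- c(control = 1, plus_half = 1 / suppression,
               minus_half_on_leg = 1 / suppression, minus_half_outside_leg = 1)
  set.seed(child_seed(cfg$seed, 9L))
  rows <- list(); idx <- 0L
  sdlog <- sqrt(log(1 + rate_cv^2))
  for (cl in names(classes)) {
    for (i in seq_len(n_per_class)) {
      idx <- idx + 1L
      planted <- base_norm_rate * classes[[cl]] *
        stats::rlnorm(1, -sdlog^2 / 2, sdlog)
      sci <- scene_config(shape = c(scene_px, scene_px),
                          pixel_size = scene_pixel_size,
                          seed = child_seed(cfg$seed, 10L + idx),
                          noise = 0.02)
      scn <- clearance_scene(area0, planted * area0, cfg$clearance_frames,
                             sci, dt = cfg$clearance_dt)
      if (from_masks) {
        tr <- measure_clearance(scn$spheroid, scn$mesothelium,
                                scn$areas$time_h, scene_pixel_size)
        nrate <- tr$normalized_rate; r2 <- tr$r_squared
      } else {
        fit <- clearance_rate(scn$areas$time_h, scn$areas$cleared_area)
        nrate <- normalized_rate(fit$rate, scn$areas$spheroid_area[1])
        r2 <- fit$r_squared
      }
      rows[[idx]] <- data.frame(id = idx, class = cl,
                                planted_norm_rate = planted,
                                normalized_rate = nrate, r_squared = r2)
    }
  }
  traces <- do.call(rbind, rows)
  groups <- group_rates(traces$normalized_rate, traces$class)
  out <- list(traces = traces, groups = groups)
  if (!is.null(cfg$out_dir)) {
    write_table(traces, cfg$out_dir, "clearance_traces.csv")
    med <- data.frame(class = names(groups$medians),
                      median_norm_rate = as.numeric(groups$medians),
                      n = as.integer(groups$n[names(groups$medians)]))
    write_table(med, cfg$out_dir, "clearance_medians.csv")
    write_manifest(cfg, file.path(cfg$out_dir, "manifest.json"),
                   list(study = "clearance", n_per_class = n_per_class,
                        base_norm_rate = base_norm_rate,
                        suppression = suppression))
  }
  out
}
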