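#!/usr/bin/env Rscript
# Velocity fields around defects: PIV on an advected texture pair
# validates the correlator, then defect-frame summaries quantify the
# inward flow at a +1/2 defect and the leg-convergent / radially outward
# flow at a -1/2 defect, against defect-free controls.

suppressMessages(library(nemaclear))
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# PIV validation on a known uniform shift (3 px = 11.25 um/h at 10 min)
cfg <- scene_config(shape = c(256L, 256L), seed = 5L)
fld <- ideal_director_field(list(), cfg)
set.seed(105)
fld$theta <- (fld$theta + pi / 6 +
                matrix(rnorm(256^2, 0, 0.15), 256, 256)) %% pi
tex <- render_cell_texture(fld, 16, cfg)
v <- piv_displacement(tex, advect_image(tex, 3, 0))
cat(sprintf("PIV check: planted 11.25 um/h, recovered %.2f um/h over %d subsets\n",
            mean(v$vx[v$mask]), sum(v$mask)))

# +1/2 defect study
vs <- run_velocity_study(run_config(seed = 2, out_dir = file.path(out, "velocity_plus")),
                         charge = 0.5, scene_px = 1024L)
s <- vs$summary
cat(sprintf("+1/2 defect (tail at %.2f rad): right-box vx %.2f, left-box vx %.2f um/h\n",
            s$tail_angle[1], s$mean_vx[s$box == "right"],
            s$mean_vx[s$box == "left"]))
cat(sprintf("  -> inward flow on both sides; control boxes mean vx %.3f um/h (n = %d)\n",
            mean(vs$controls$mean_vx), length(unique(vs$controls$location))))

# -1/2 defect study
vm <- run_velocity_study(run_config(seed = 2, r_min = 250, r_max = 900,
                                    out_dir = file.path(out, "velocity_minus")),
                         charge = -0.5, scene_px = 2048L)
m <- vm$summary
cat(sprintf("-1/2 defect: v_phi A %+.2f, B %+.2f um/h; v_r on-leg %+.3f, off-leg %+.2f um/h\n",
            m$v_phi_A, m$v_phi_B, m$v_r_on_leg, m$v_r_off_leg))
cat("  -> cells converge on the legs and move outward elsewhere\n")
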