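#!/usr/bin/env Rscript
# Generate the synthetic scenes used throughout the analysis: a director
# field with a +1/2 / -1/2 defect pair rendered as a cell texture, a
# nuclei image with a density gradient, and a clearance mask stack.
# Images go to results/scenes as 16-bit TIFF with JSON ground truth.

suppressMessages(library(nemaclear))
out <- "results/scenes"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 1L

cfg <- scene_config(shape = c(512L, 512L), pixel_size = 0.625, seed = seed,
                    noise = 0.1)
ext <- (512 - 1) * cfg$pixel_size
defs <- list(planted_defect(ext * 0.3, ext * 0.5, +0.5, phase = 0.3),
             planted_defect(ext * 0.7, ext * 0.5, -0.5, phase = 1.0))
fld <- ideal_director_field(defs, cfg)
tex <- render_cell_texture(fld, streak_length = 12, cfg)
write_image_stack(tex, file.path(out, "monolayer_texture.tif"))

ncfg <- scene_config(shape = c(800L, 800L), pixel_size = 1, seed = seed)
dens <- function(x, y) {
  r <- pmin(sqrt((x - 400)^2 + (y - 400)^2), 400)
  pmax(1500 - 4 * (r - 200), 0)
}
nuc <- nuclei_image(dens, spot_sigma = 4, intensity_per_cell = 1000, ncfg)
write_image_stack(nuc$image, file.path(out, "nuclei.tif"))

ccfg <- scene_config(shape = c(256L, 256L), pixel_size = 3, seed = seed,
                     noise = 0.02)
scn <- clearance_scene(1e4, 2500, 15, ccfg)
write_image_stack(scn$spheroid, file.path(out, "spheroid_channel.tif"))
write_image_stack(scn$mesothelium, file.path(out, "mesothelium_channel.tif"))
utils::write.csv(scn$areas, file.path(out, "clearance_areas.csv"),
                 row.names = FALSE)

truth <- list(
  seed = seed,
  defects = lapply(defs, function(d) d[c("x", "y", "charge", "phase")]),
  nuclei = list(n_cells = nrow(nuc$positions), intensity_per_cell = 1000),
  clearance = list(spheroid_area0 = 1e4, clear_rate = 2500))
jsonlite::write_json(truth, file.path(out, "ground_truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat("Simulated scenes written to", out, "\n")
cat(sprintf("  monolayer texture: 512x512 px, defects at x = %.0f and %.0f um\n",
            defs[[1]]$x, defs[[2]]$x))
cat(sprintf("  nuclei image: %d cells planted\n", nrow(nuc$positions)))
cat("  clearance stack: 15 hourly frames, planted rate 2500 um^2/h\n")
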