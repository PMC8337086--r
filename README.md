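# nemaclear

Topological defects in mesothelial cell monolayers and their effect on
ovarian-cancer spheroid clearance.

Confluent mesothelial cells are elongated and align into nematic
domains described by a director field θ ∈ [0, π). Where the alignment
breaks down, half-integer topological defects appear: +1/2 "comet"
defects with one symmetry axis and −1/2 "trefoil" defects with three
legs 120° apart, classified by the winding number

  q = (1/2π) ∮ dθ  ∈  {+1/2, −1/2}.

These defects reorganize the monolayer: cell velocity converges on
+1/2 cores (inward flow along the tail axis from both sides) and on the
legs of −1/2 defects (with net outward flow between legs), cell density
rises at +1/2 cores and falls at −1/2 cores, and ovarian-cancer
spheroids clear the mesothelial layer more slowly wherever the flow
converges. `nemaclear` implements the full measurement chain for these
claims, for anyone analyzing collective order in monolayer microscopy:

* **director** — orientation and coherence from image texture via a
  derivative-of-Gaussian structure tensor;
* **defects** — detection by plaquette winding + ring confirmation,
  phase/axis estimation, and frame-to-frame tracking;
* **flow** — subset-correlation PIV (64 px subsets, 16 px grid) with
  2-D Gaussian subpixel peak fitting, and the defect-frame summaries:
  500 × 750 μm boxes around +1/2 defects, angular/radial sector
  averages in a 250–1800 μm annulus around −1/2 defects;
* **density** — cell counts from integrated nuclear fluorescence in
  circles of radius R (10–350 μm), with density-vs-R regression slopes;
* **clearance** — spheroid and cleared-area segmentation, linear
  clearance-rate fits normalized by initial spheroid area (h⁻¹), and
  location classification (control / +1/2 / −1/2-on-leg /
  −1/2-outside-leg, 750 μm qualification radius);
* **stats** — rank-sum (exact for small n), Kruskal–Wallis + Bonferroni,
  ANOVA, Anderson–Darling, regression CIs;
* **synthgen** — synthetic scenes with planted ground truth (director
  fields, cell textures, flow templates, nuclei images, clearance
  stacks) so every stage is testable without microscopy data.

## Worked example

Plant a −1/2 defect, detect it from the field, and measure its legs:

```r
library(nemaclear)

cfg <- scene_config(shape = c(512, 512), pixel_size = 0.625, seed = 1)
ctr <- (512 - 1) * 0.625 / 2
fld <- ideal_director_field(list(planted_defect(ctr, ctr, -0.5, phase = 0.3)), cfg)

(dets <- detect_defects(fld))
#>          x        y charge     phase core_coherence flag
#> 1 159.6875 159.6875   -0.5 0.3000021              1

sort(defect_axes(fld, dets[1, ])) * 180 / pi
#> [1]  11.464 131.452 251.476     # legs; adjacent separations ~120 deg
```

The full studies live in `analysis/` as numbered drivers over the
package (each writes its tables under `results/`):

```sh
Rscript analysis/01_simulate_scenes.R   # synthetic scenes + ground truth
Rscript analysis/02_defect_geometry.R   # detection, axes, tracking
Rscript analysis/03_velocity_study.R    # PIV + defect-frame flow summaries
Rscript analysis/04_density_study.R     # density-vs-R slopes, 0 h vs 10 h
Rscript analysis/05_clearance_study.R   # clearance-rate cohort comparison
```

Sample output (seeded, so identical on re-run):

```
+1/2 defect (tail at 3.74 rad): right-box vx -6.54, left-box vx 6.57 um/h
  -> inward flow on both sides; control boxes mean vx 0.071 um/h (n = 21)
-1/2 defect: v_phi A +3.95, B -3.95 um/h; v_r on-leg +0.010, off-leg +3.95 um/h

Density slope (cells/mm^2 per um), replicate-mean profiles, n = 6:
  t0: -0.315 [-0.694, +0.064]      # CI includes 0: no accumulation yet
  t1: -3.781 [-4.582, -2.979]      # negative: cells accumulated at the core

Median normalized clearance rate (1/h), n = 20 spheroids per class:
  control 0.202   plus_half 0.105   minus_half_on_leg 0.130   minus_half_outside_leg 0.215
  plus_half vs control: corrected p = 6.7e-07   (planted factor-2 suppression)
```

Negative right-box `vx` with positive left-box `vx` is the inward-flow
signature of a +1/2 defect; positive A-sector angular velocity with
negative B means cells converge on the −1/2 legs; the clearance
medians recover the planted suppression on +1/2 cores and −1/2 legs
and its absence outside the legs.

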