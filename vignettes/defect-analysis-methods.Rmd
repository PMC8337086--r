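---
title: "Quantifying topological defects in mesothelial monolayers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying topological defects in mesothelial monolayers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nemaclear)
```

## The model

Confluent mesothelial cells are elongated and align with their
neighbours, so the monolayer carries a *nematic* orientation field: at
every point a headless angle $\theta \in [0, \pi)$ giving the local
cell-axis direction. Points where $\theta$ is discontinuous are
topological defects, characterized by the winding number (charge)

$$ q = \frac{1}{2\pi} \oint d\theta, $$

the total director rotation around a loop enclosing the point. Because
$\theta \equiv \theta + \pi$, half-integer charges are allowed, and
$\pm 1/2$ are the generic defects in cell monolayers. A $+1/2$ defect
has a single symmetry axis (the "comet tail"); a $-1/2$ defect has
three ("legs") separated by $120^\circ$. Around an ideal defect at the
origin the director is

$$ \theta(\mathbf{r}) = q\,\phi + \theta_0, $$

with $\phi$ the polar angle and $\theta_0$ a phase. An axis is a
direction along which the director is radial, $(1-q)\phi \equiv
\theta_0 \pmod \pi$: one solution for $q = +1/2$, three (spaced
$2\pi/3$) for $q = -1/2$.

The package measures how these defects shape three observables in the
monolayer: the local cell velocity (net inward flow along the tail axis
of $+1/2$ defects; convergence onto the legs plus net radial outflow
between the legs of $-1/2$ defects), the local cell density
(accumulation at $+1/2$ cores, depletion at $-1/2$ cores), and the rate
at which ovarian-cancer spheroids clear the mesothelial layer
(suppressed where the flow converges: on $+1/2$ cores and on $-1/2$
legs).

## Director estimation

Orientation is estimated with the gradient structure tensor: the image
is filtered with derivative-of-Gaussian kernels at scale
`gradient_sigma` (default 2 px) and the outer products of the gradients
are averaged over a Gaussian window `window_sigma` (default 16 px,
about one cell width at the default 0.625 um/px). The director is the
eigenvector of the *smaller* eigenvalue — the direction of least
intensity variation, i.e. the streak axis — and coherence
$(\lambda_1-\lambda_2)/(\lambda_1+\lambda_2)$ serves as a local order
parameter in $[0,1]$.

Two numerical choices matter here:

* Gradients use derivative-of-Gaussian filters rather than finite
  differences. Central differences have a direction-dependent transfer
  function that biases orientation estimates toward the diagonal by
  more than a degree at cell-scale wavelengths; the Gaussian derivative
  suppresses the offending frequencies and brings the bias on analytic
  stripe patterns below 0.05 degrees.
* All angle averaging — downsampling, interpolation on rings — is done
  on the coherence-weighted nematic tensor $(\cos 2\theta, \sin
  2\theta)$, never on raw angles, so that $10^\circ$ and $170^\circ$
  average to $0^\circ$, not $90^\circ$.

Images are flipped to a y-up mathematical frame on load, with angles
measured counterclockwise from +x, so that counterclockwise angular
velocity is positive without sign gymnastics downstream.

## Defect detection, axes, and tracking

Every 2x2 plaquette whose wrapped director differences wind by a
half-integer becomes a candidate; candidates within `merge_radius`
(default 3 grid nodes) are clustered and the cluster centroid is
confirmed by re-measuring the winding on a ring of `loop_radius`
(default 5) nodes. Wrapping differences into $(-\pi/2, \pi/2]$ makes
the loop sum an exact multiple of $\pi$, so reported charges are exact
half-integers; anything else is flagged "unresolved" rather than
coerced (full-integer defects are reported flagged, not forced to
$\pm 1/2$). Defects closer than two ring radii are flagged as
unresolved neighborhoods.

The phase $\theta_0$ is fitted by least squares of the unwrapped
doubled angle against $2q\phi + 2\theta_0$ on a ring. Symmetry axes are
then located *independently* by root-finding the radial-director
residual $\theta(\phi) - \phi \pmod \pi$ on a 720-point ring: the three
$-1/2$ legs are three separate roots, so their $120^\circ$ separations
are a measurement, not an algebraic identity of the fit. For $+1/2$
the single root fixes the axis line and the defect polarization
$\mathbf p = (\partial_x Q_{xx} + \partial_y Q_{xy},\; \partial_x
Q_{xy} - \partial_y Q_{yy})$ of the coherence-weighted tensor picks the
tail end: the tail points along $-\mathbf p$, the side where the
director bends around the core. This convention was validated visually
on rendered synthetic scenes; flipping it would flip the sign of the
box-averaged $v_x$ pattern, which the sign tests would catch.

Tracking is greedy nearest-neighbour linking frame to frame, same
charge only, capped at `max_link`; ties break by distance then
row-major order so results are deterministic. Mean speed is path length
over elapsed time.

## Velocity analysis

Velocities come from zero-normalized cross-correlation of 64x64 px
subsets on a 16 px grid (10 um at the default pixel size), one vector
per subset per frame pair, divided by the frame interval. The integer
peak is refined by a 2-D log-paraboloid fit over the 3x3 peak
neighbourhood; the 2-D fit matters because streaked cell textures
produce elongated, tilted correlation peaks for which independent
per-axis 3-point fits are biased. Subsets with correlation peak below
0.3, a border peak, or constant intensity are masked invalid and
excluded from every average.

A note on test conditions: a *perfectly uniform* noise-free streak
texture is degenerate for any correlator — the correlation surface is a
ridge along the streak axis (the aperture problem) and the along-streak
displacement component is unconstrained. Accuracy tests therefore use
textures with 0.15 rad of director jitter, which restores within-subset
structure; real monolayers always have such variation. Under that
condition planted uniform shifts are recovered within 0.2 px per
component.

For each $+1/2$ defect the field is rotated (positions and vectors) so
the tail points along +x, and velocities are averaged in four
500 um x 750 um boxes immediately left, right, above, and below the
core, with inner edges 25 um out so opposing boxes are 50 um apart.
"Immediately adjacent" is pinned down by the 50 um separation between
the left and right regions; we interpret that symmetrically for all
four boxes. For each $-1/2$ defect velocities are decomposed into
radial and angular components about the core; the annulus between
`r_min` = 250 um and `r_max` = 1800 um is split by the three legs into
six sectors, excluding a 45 um-half-width band along each leg
("within 45 um of a leg" is read as perpendicular distance to the leg
ray). Angular velocity is averaged over the two alternating sector
groups A and B and radial velocity over the on-leg and off-leg regions.

The A/B labeling is chosen so that flow converging on the legs gives
positive (counterclockwise) mean angular velocity in A: A is the
half-sector from which the nearest leg lies *counterclockwise* (the
clockwise side of each leg). The observed pattern — A positive, B
negative, cells moving toward the legs — forces this assignment; the
alternative labeling (A on the counterclockwise side) would make the
two statements contradict each other.

Controls apply the same box geometry at seeded random defect-free
locations (21 by default).

## Density analysis

Cell counts come from integrated nuclear fluorescence: the mean
single-cell intensity is calibrated from 15 randomly sampled detected
nuclei (background = image mode, integration over the full spot
window), and the count inside a circle of radius $R$ is the summed
intensity over the circle divided by that calibration. Density is the
cumulative count over $\pi R^2$, reported in cells/mm^2, profiled for
$R$ from 10 to 350 um, and summarized by the OLS slope of density on
$R$ with a t-based 95% CI. Negative slope means denser at the core.
Small circles hold few cells (a 10 um circle at 1500 cells/mm^2 holds
0.5 cells on average), so single-scene slopes are Poisson-noisy;
profiles are averaged over replicate scenes (n = 6 in the bundled
study) before fitting, and the planted accumulation effect in the
two-timepoint study was sized at design time to be detectable under
that noise with n = 6.

## Clearance analysis

The spheroid channel is segmented per frame by Otsu threshold, largest
connected component, holes filled; the cleared region is segmented the
same way on the inverted mesothelial channel (a user-supplied manual
mask overrides this, since the original measurement was manual).
Cleared area grows approximately linearly, so the rate is the OLS slope
of cleared area on time over 15 hourly frames, normalized by the
initial spheroid area to give a size-independent rate in 1/h.

Spheroids are classified by defect proximity using a 750 um
qualification radius (promoted from the imaging-selection rule to the
class definition): `plus_half` requires positive projection on the
tail axis; `minus_half_on_leg` vs `minus_half_outside_leg` splits at
45 um perpendicular distance from a leg ray; everything else is
control; the nearest qualifying core wins, ties to $+1/2$. Cohorts are
compared by class medians, a Kruskal-Wallis omnibus test, and pairwise
rank-sum tests against control with Bonferroni correction (factor =
number of comparisons actually run, recorded in the output).

## Statistics

Wilcoxon rank-sum tests use the exact permutation distribution when
both groups have at most 10 untied observations and the tie-corrected
normal approximation otherwise; the two agree within 0.02 from n = 8
per group (below that the exact path is always taken). One-way ANOVA
with pooled-variance pairwise t tests and Bonferroni correction, the
case-3 Anderson-Darling normality test (mean and SD estimated,
small-sample correction), and OLS slope CIs round out the toolbox. All
tests are two-sided and deterministic given their inputs.

## The synthetic-scene generator

Every stage is validated against scenes with planted ground truth:

* **Director fields.** Multi-defect fields superpose additively in the
  angle (the standard nematic construction); director noise is
  Gaussian on the angle, equivalent to a wrapped distribution on
  $2\theta$, respecting the nematic symmetry; coherence is set to the
  corresponding order parameter $e^{-2\sigma^2}$. Cores closer than
  20 px are rejected.
* **Textures.** Line-integral-convolution-style streaking of seeded
  white noise along the local director emulates the elongated-cell
  texture; it reproduces orientation, not cell morphology.
* **Flows.** Kinematic templates with the observed sign structure: in
  the $+1/2$ defect frame $v_x = -v_0\,\mathrm{sign}(x)\,e^{-r/\ell}$,
  $v_y = 0$; around a $-1/2$ defect the angular component drives each
  point toward its nearest leg and the radial component is $+v_0
  e^{-r/\ell}$ off the legs and zero on them. These are *not*
  active-nematic hydrodynamics — no Q-tensor PDE is integrated — and
  flow magnitudes are free parameters ($v_0$ = 10 um/h, $\ell$ =
  500 um in the bundled studies) because the source observations are
  qualitative sign patterns.
* **Nuclei.** An inhomogeneous Poisson point process (thinning) with
  Gaussian spots of fixed integrated intensity; no hard-core exclusion
  radius, so spots may overlap — calibration tests use sparse fields.
* **Clearance scenes.** A constant-area spheroid disk and a cleared
  disk whose area grows linearly at the planted rate, with optional
  fractional area noise per frame; the analytic per-frame areas are
  returned alongside the rendered masks, so estimator tests can
  separate fitting error from segmentation error.

All randomness flows from the single seed in `scene_config` through
per-component child seeds; identical (config, seed) gives bit-identical
scenes, tables, and statistics.

What passing on these scenes does *not* show: robustness to uneven
illumination, imaging artifacts, cell division and extrusion, or
non-stationary flows — none of which the generator emulates. The
velocity templates encode only the observed sign structure, so
magnitude-level agreement with real monolayers is out of scope by
construction.

## Problem sizes and defaults

The bundled studies use 512-2048 px scenes, 6 replicate nuclei scenes
per timepoint, 20 spheroids per clearance class, and 21 velocity
controls; these sizes were chosen so that each study's planted effect
is comfortably detectable while a full run of every analysis script
completes in well under a minute. Defaults throughout (subset 64 px,
spacing 16 px, boxes 750x500 um, gap 50 um, exclusions 250/45 um,
outer radius 1800 um, radii 10-350 um, qualification radius 750 um,
15 hourly frames, 15 calibration nuclei) are carried in `run_config()`
and echoed into every run manifest.

## Known limitations

* Winding measurement assumes the director varies by less than
  $\pi/2$ between adjacent loop nodes; severely under-resolved or
  extremely noisy fields can alias a charge.
* The tail-sign convention relies on the polarization estimate at the
  core, which degrades when another defect sits within the ring radius
  (such records are flagged).
* Cleared-area segmentation assumes a single dominant cleared region;
  fragmented clearance would need manual masks.
* The density estimator counts intensity, so debris or staining
  heterogeneity in real images would bias counts; the synthetic tests
  cannot detect that class of error.
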