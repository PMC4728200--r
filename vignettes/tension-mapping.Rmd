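---
title: "Image-based tension mapping of the adherent cell cytoskeleton"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-based tension mapping of the adherent cell cytoskeleton}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tensionmap)
```

## The model

An adherent cell spread on a rigid substrate holds itself under tension: myosin
motors contract the actin network, and the resulting forces are transmitted to
the substrate through focal adhesions (FAs). `tensionmap` reconstructs that
force balance from three registered fluorescence channels of a single fixed
cell — actin (phalloidin), an FA marker (vinculin), and the nucleus (DNA
stain) — and converts the actin image into a quantitative map of intracellular
tension.

The reconstruction has four parts.

**Nodes from pixels.** The frame is partitioned into 2x2 pixel blocks
(`binning = 2`), each block becoming one mechanical node; at the reference
pixel pitch of 0.29 um/px this gives a node spacing `d0 = 0.58` um. Blocks
covered by the binarized FA marker become immobilized *vinculin* anchors,
blocks inside the nucleus mask become *nucleus* nodes, and the remaining
blocks with actin signal become *actin* nodes labelled 1..10 by their
normalized gray value c (right-closed bins of width 0.1; label 10 is the
densest actin). Marker components are rasterized area-conservingly: each
connected adhesion claims the blocks it covers most, one per `binning^2`
pixels of its area and at least one — an any-pixel rule would dilate every
adhesion by half a block per side and make the calibrated stiffness depend on
the model resolution.

**Pre-strained tensile interactions.** Neighboring nodes within the
visibility threshold `g_v = 1.1 d0` (exactly the 4-neighborhood on the node
grid) are joined by elastic-band interactions with creation gap `g0`,
pre-strain `epsilon0 = 0.2` (the measured contraction of stress fibers in
static adherent cells), and stiffness proportional to local actin density:

\[ T(g) = K\left(\frac{g - g_0}{g_0} + \varepsilon_0\right) \quad
   \text{for } g > (1-\varepsilon_0)g_0, \qquad T = 0 \text{ otherwise,} \]

with `K_i = a * 0.1 * i` for two actin nodes of (weakest) label i, the
actin-side label for actin-vinculin and actin-nucleus pairs, and `10 a` for
nucleus pairs. The single coefficient `a` (nN) converts image density into
mechanics and is the unknown of the inverse problem.

**Compression bearing.** Each movable node carries a spherical contactor of
radius `0.4 d0`, so two neighbors touch after ~20% mutual approach — exactly
when their tensile band slackens. Contacts obey the frictionless rigid law
(gap >= 0, reaction >= 0, gap x reaction = 0), regularized by a linear
penalty (`100 a / d0` by default). This contact network stands in for
microtubule-like compression bearing; runs with it are the *MT+* scenario,
runs without it *MT-*. Contactors sit on movable nodes only: compression
bearing is a cytoskeletal function, and the anchor reactions should report
what the contractile network transmits to the adhesion (placing contactors on
the immobilized anchors lets collapsing material pile against them and bury
the adhesion force sum under arching contact chains).

**Inverse calibration.** FA areas predict traction forces linearly
(5.5 nN/um^2, adhesions of at least 1 um^2; smaller adhesions do not scale
with force and are excluded by default, although the 0.5-1 um^2 class can
optionally contribute a fixed 15 nN each). The measured sum `F_measured` is
matched by sweeping `a` over {1, 4, 8, 15}, relaxing the network at each
value, fitting the near-perfect line `F = alpha a - beta`, and solving
`a = (F_measured + beta)/alpha`. At the solved `a`, tensions are summarized
as resolution-independent *cross-linear* densities: `T_cl = T/d0`, with
`T_cl_max = a epsilon0 / d0` the density at maximal actin density (c = 1).
Because the pre-stressed network relaxes only slightly, `a/d0` is the
equivalent stiffness-based scale, and both are reported.

**Probes.** With `T_cl_max` in hand, tension is measured directly on the
image: a segment drawn across a fiber of width w with mean gray value c-bar
carries `T = T_cl_max * c_bar * w`. Probes use the full 256-level normalized
image, not the 10-label quantization. Whole-cell sections give the
intracellular tonus, and a fiber's equivalent Young's modulus follows from
`E = T / (pi (w/2)^2 epsilon0)` (nN and um give kPa directly).

## Solving the quasi-static problem

The target of the computation is the static equilibrium of a fixed cell, not
a contact-dynamics trajectory. The integrator is a damped semi-implicit Euler
scheme (`v <- damping (v + F/m dt); x <- x + v dt`) run for a fixed 600 steps
of 0.5 us; node masses default to 0.8 pg (the water volume of a contactor
sphere). With those constants, however, a literal explicit integration cannot
work: the penalty contact stiffness and the 10x nucleus springs sit far above
the explicit stability bound, while a stability-bounded damping advances the
soft global contraction mode by under a percent in 600 steps. `relax()`
therefore defaults to classic dynamic relaxation
(`solver_config(precondition = TRUE)`):

* fictitious per-node masses proportional to the local incident stiffness
  (the penalty term counts only while a node is actually in contact), so
  every node advances at the same fraction of its local stability limit —
  the static solution is mass-independent, so this changes the path, not the
  answer;
* momentum damping 0.95 with kinetic-energy restarts (velocities are zeroed
  whenever kinetic energy peaks), the standard form-finding scheme for
  pre-stressed networks;
* a per-step displacement cap of `0.1 d0`, so fast nodes cannot punch through
  a contact in one step;
* viscous normal damping inside active contacts (it vanishes as v goes to 0,
  leaving the penalty law intact at equilibrium, and is clamped so a contact
  never turns adhesive);
* a terminal quench (damping drops to 0.5 over the last fifth of the run)
  that freezes the state into its equilibrium instead of chattering.

`precondition = FALSE` recovers the plain literal scheme, which the
single-step unit tests exercise. The solver contains no randomness; identical
inputs give bit-identical output. Convergence is reported (maximal residual
force on free nodes, maximal contact penetration, the complementarity
residual) but not enforced: the default protocol is a fixed 600 steps, and
the residual tells you what that bought.

The *free run length* — the displacement of free nodes per step — is recorded
as a series; its run average is the stability index used to compare
scenarios (a jammed MT+ model moves less over the computation than its
tension-only MT- counterpart). The final-step value alone mostly measures how
early the solver finished and is reported for completeness.

## The synthetic cell

No imaging data ships with the package; `generate_cell()` renders image
triplets with known ground truth. Stress fibers are straight segments with a
Gaussian cross-profile whose FWHM equals the nominal width (a
diffraction-limited look), max-composited (never summed) over a uniform
dendritic background inside an elliptical cell support, plus an optional
circular actin belt and seeded Gaussian intensity noise clipped to [0, 1].
Noise is applied inside the cell support, where fluorescence shot noise
lives; the dark exterior stays dark so the footprint derivation stays honest.
The FA channel is a set of disks of requested areas (overlapping disks merge
with a warning), the nucleus an ellipse.

`reference_cell()` is the fixed specification used by the test-suite: a
62 x 35 um canvas at 0.29 um/px holding an elliptical cell of about 60 x 33 um,
five stress fibers of widths 0.85-1.75 um criss-crossing the spread area and
terminating in eight FA disks of 1.2-1.5 um^2 near the cell periphery, a
circumferential belt, and a 12 x 8 um nucleus. Two design choices matter:

* *Anchorage at the periphery.* Adherent cells anchor at their spread edge;
  if free contractile material sits outboard of the anchors it collapses onto
  them and loads them with pile-up compression instead of network tension.
* *Disk areas.* The areas put the FA-area force sum inside the model's
  response over the swept `a` range, so the calibration interpolates rather
  than extrapolates.
* *Probe stations.* The cross-section probes of the two oblique fibers sit
  off the geometric midpoint (`probe_t`) so no crossing fiber or belt
  contaminates the section.

What the generator does **not** emulate: real point-spread functions (the
Gaussian profile is a convenient stand-in), out-of-focus light, uneven
illumination, textured dendritic actin, curved fibers, or multi-cell scenes.
Tests passing on synthetic cells show the pipeline's bookkeeping is correct
under known geometry; they cannot certify segmentation quality on real
micrographs.

## Numerical choices and tolerances

* **Normalization** subtracts the 1st-percentile intensity (robust to hot
  pixels) and rescales the maximum to 1; it is idempotent whenever at least
  a percent of the frame is background.
* **Label bins are right-closed**: c = 0.1 maps to label 1, c = 1 to label
  10, c = 0 to no node. A 1e-9 guard absorbs floating-point edge cases at
  the bin boundaries.
* **Area filter** is inclusive: exactly 1 um^2 is retained.
* **Contact penetration** at equilibrium stays well under 1% of d0 with the
  default penalty; the run warns if it does not and suggests a higher
  penalty.
* **Probes** sample at `pixel_pitch/2` with bilinear interpolation, which
  makes them rotation-invariant to about 1%. Pixelation and interpolation
  average gray values, so probes under-read thin fibers — by about 2% at
  1.6 um width and about 5% at 0.85 um, never over-reading. This is the
  resolution-averaging effect that motivates the recommendation to probe
  only sections wider than 0.6 um (widths below it warn).
* **Fixed-step protocol.** Scenario comparisons (MT- pulls harder than MT+;
  MT+ moves less) are made at the standard 600-step protocol from rest. At
  full convergence the two scenarios differ by only a few percent on the
  synthetic reference cell and the FA-sum ordering can invert: the ordering
  is a property of the calibration protocol's mid-transient regime, which is
  also where the printed calibration lines with nonzero intercepts and
  R^2 < 1 live.

## Resolution independence and its limits

Dividing by `d0` makes cross-linear tension comparable between models of
different mesh size: rebuilding the same cell with half or double node
spacing (`binning` 1 or 4) changes every per-interaction tension but should
leave `T_cl_max` in place. In practice this holds to about 10% — and only
when the adhesions are well resolved (several node spacings across) and each
model is relaxed to a comparable convergence state; the test-suite checks it
on a uniform-density phantom cell with large adhesion patches. For adhesions
near the node spacing, rasterization quantizes the anchor geometry and the
property degrades — the same reason sub-micrometer adhesions are excluded
from the force-area law.

## Known limitations

* The model is two-dimensional and static: no fiber viscoelasticity or
  hyperelasticity, no dynamic loading, no 3D stress architecture.
* Stress-fiber probes are user-drawn; the package does not trace fibers.
* The compression network is a stand-in for microtubules: spheres with a
  frictionless penalty contact, not filaments with bending stiffness.
* Calibration quality is bounded by the FA force estimate: the area-force
  coefficient carries substantial biological scatter, and sub-micrometer
  adhesions (potentially large forces, excluded from the law) bias
  `F_measured` low — and with it every tension in the map, linearly.
* Channels are assumed registered; no alignment is performed.

## A worked run

```{r, eval = FALSE}
cell <- generate_cell(reference_cell())
fit <- fit_cell_tension(cell)       # MT+ scenario, sweep a in {1, 4, 8, 15}
fit
coef(fit)

# tension across each synthetic fiber, measured on the image
predict(fit, cell$truth$fibers[, c("px0", "py0", "px1", "py1")] |>
  setNames(c("x0", "y0", "x1", "y1")))
```
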