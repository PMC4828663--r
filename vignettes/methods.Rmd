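---
title: "Methods: simulating persistent AF and virtual ablation on a synthetic left atrium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating persistent AF and virtual ablation on a synthetic left atrium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model overview

`atrialab` reproduces, at desk scale, the computational workflow of an
in-silico study of radiofrequency ablation (RFA) strategies for persistent
atrial fibrillation (pAF): a fibrotic left-atrial (LA) substrate is built,
fibrillation is induced by rapid pulmonary-vein (PV) pacing or cross-field
stimulation, rotor phase singularities (PSs) are mapped, and three families
of virtual lesions are applied and scored. The original study ran on a
patient-CT-derived bilayer mesh (363k nodes, 333 um edges) with a
population-averaged late-gadolinium-enhancement (LGE) atlas; neither input
is distributed, so this package generates a synthetic stand-in that
preserves every mechanism the experiments rely on, and runs the physics on
meshes a single CPU can integrate in minutes.

The pipeline is organized as numbered drivers under `analysis/` (substrate,
single cell, initiation, phase mapping, ablation, correlations), each a thin
narrative over exported package functions.

# Synthetic geometry

The default geometry is a 50 x 50 mm monolayer sheet at 0.5 mm mean edge
length (configurable down to 0.333 mm) with four circular PV ostium holes,
two per half. The lower half is "posterior" (subdivisions 1-4 by
x-quartile), the upper "anterior" (5-8), mirroring the eight-subdivision
regional analysis of clinical PS mapping. The outer rectangle stands in for
the mitral annulus: linear lesions and streamlines terminate there. An
ellipsoidal-cap variant (`dome_height_mm`) exists for curvature checks; all
algorithms are surface-generic (P1 elements in 3D).

Two features of the real anatomy are modeled explicitly because the study's
initiation mechanism depends on them:

* **Fiber rotation at the PV bases.** Fibers are uniform in the body and
  rotate by 90 degrees inside a 2 mm band around each ostium. The band
  width is not stated in the source; 2 mm spans several elements at the
  default resolution, which is what the conduction-block mechanism needs.
* **PV/LA repolarization gradient.** PV sleeves carry the PV ionic variant
  (below), giving a shorter APD in the sleeve than in the body.

What the synthetic geometry deliberately does **not** emulate: patient
anatomy (curvature, wall thickness, appendage trabeculation), the right
atrium and its conduction system, and the bilayer endo/epi construction
(an optional resistively-coupled two-layer mode exists,
`couple_layers()`, but all experiments run monolayer). Quantities tied to
the true anatomy - sinus activation-time tables, absolute rotor positions -
are therefore out of reach by design; mechanisms and regional statistics
are in reach.

# LGE likelihood and fibrosis

`build_lge_map()` draws a smooth sum of ~30 Gaussian bumps (3-8 mm SD) and
rescales it per subdivision so the normalized per-subdivision densities
(subdivision mean / max subdivision mean) match a target 8-vector within
0.02. The default targets are the published regional fibrosis densities
shipped as `la_reference_densities`. The base level (densest subdivision
mean 0.45) keeps values inside [0, 1] after scaling.

Fibrosis is interstitial: mesh *edges* are selected stochastically and then
decoupled, rather than assigning slow or unexcitable elements. Edge `e`
with acute fiber angle `theta` and likelihood `L` (mean of its two adjacent
triangles) is selected iff

    alpha * (4 cos^2 theta + sin^2 theta) * L > u,   u ~ U(0, 1),

so edges parallel to fibers are exactly four times likelier than
perpendicular ones at equal likelihood. The comparison is used literally
(probabilities above 1 simply always select); a per-edge draw in edge index
order makes realizations reproducible and lets tests replay the stream.

`calibrate_alpha()` targets a median connected-component length of 670 um
(the interstitial-fibrosis scale in aging fiber bundles) by bisection in
log-alpha. The objective - the mean over 20 seeded realizations of the
per-realization median component length - reuses one uniform matrix across
alpha values, making it deterministic and monotone, so bisection is exact
up to the discreteness of component lengths. At 0.5 mm resolution
component lengths are sums of 440/620 um edges; the seed-averaged
objective is dense enough near 670 um for the +/- 50 um tolerance.

`split_edges()` imposes the no-flux discontinuities: around every node
touched by selected edges the triangle fan is cut at each selected edge and
each wedge receives its own node copy (coordinates unchanged, so area is
conserved exactly). A node whose closed fan is cut only once (an interior
crack tip) is additionally cut opposite the crack - the deliberate
tie-break that guarantees even a single selected edge decouples its two
triangles. Fully-selected triangles are removed. Because P1 elements
exchange flux through shared nodes, connectivity is audited on the
node-sharing graph; fibrotic loops that would electrically isolate a patch
are re-attached at one junction node (union-find over components, reported
via a message). Tissue the solver sees therefore remains one conducting
component.

# Ionic model and regional variants

Membrane kinetics are the Courtemanche-Ramirez-Nattel human atrial model
(21 state variables), written from the published equations in `src/`.
Parameter policy, applied in order:

1. tissue adjustments: `gNa x 2` (upstroke velocity in coupled tissue) and
   `gK1 x 0.8` (rate adaptation);
2. pAF electrical remodeling: `Ito x 0.5`, `IKur x 0.5`, `ICaL x 0.3`.
   The source study cites these from the remodeling literature without
   printing numbers; the adopted triple is the standard set from the cited
   work and is exposed via `make_region_params()` for revision;
3. regional variants: PV sleeves `gto x 0.75, gCaL x 0.75, gKr x 2.4,
   gKs x 1.87, gK1 x 0.67`; LA appendage `gKr x 1.6` relative to its
   right-sided counterpart.

Finer regional repolarization gradients lived in unavailable supplementary
tables; only the main-text classes are asserted, and
`extra_multipliers` provides the hook for per-region tables. Large pAF
increases of IK1 are deliberately absent (the model's APD is highly
sensitive to gK1). With these defaults the package measures (analysis step
2): baseline APD90 ~ 288 ms at CL 1000; remodeled LA ~ 192 ms and PV
~ 118 ms at CL 700 - the PV < LA ordering that gates burst breakthrough.

Integration is Rush-Larsen for the twelve voltage-dependent gates (plus
fca/u/v on their own time constants) and forward Euler for concentrations
and voltage, default dt 20 us (25 us offered for speed). Tissue runs use
voltage-tabulated gate coefficients (0.02 mV grid, linear interpolation);
an exact-kinetics path exists and the suite checks the two agree to
sub-millivolt accuracy.

# Monodomain solver

P1 finite elements on the triangulated surface with per-triangle tensor
`D_l f f' + D_t (I - f f')`. Conductivities (S/m) convert to diffusion
(mm^2/ms) via `D = sigma / (beta Cm)` with `beta = 1400 /cm`,
`Cm = 1 uF/cm^2`. The source states no tissue conductivities (they were in
supplementary tables), so defaults are calibrated, not asserted: sigma_l =
0.22 S/m gives ~ 68 cm/s longitudinal conduction at the working 0.5 mm
resolution (~ 70 cm/s is physiological atrial CV), with sigma_t =
sigma_l / 4. A 0.001 S/m floor is enforced everywhere; ablated elements
sit exactly at the floor - lesions are conductivity floors, not element
removals. Split edges carry no flux automatically because the duplicated
nodes share no degrees of freedom.

Numerical choices: explicit (lumped-mass) diffusion - stable here because
`dt << h^2 / 4 D_max` (0.02 ms vs ~ 0.4 ms at 0.5 mm); frames recorded at
1 ms for phase analysis; stimuli are 2 ms, -30 pA/pF transmembrane current
over ~1-1.5 mm discs (the source does not specify its stimulus). Activation
is the -40 mV upward crossing, linearly interpolated between frames; nodes
that never cross report NA.

Degenerate inputs are rejected at assembly (triangle area < 1e-12 mm^2) and
divergence (non-finite Vm) aborts with the last good time.

# Protocols

Sinus rhythm is periodic pacing at 86 bpm at an "earliest LA activation"
surrogate site just below the right superior PV; the first stimulus is at
t = 0. The burst protocol paces the chosen PV sleeve five beats at CL
160 ms, coupled 240 ms (RSPV) or 400 ms (LSPV) after the reference sinus
stimulus - the coupling is measured from the sinus *stimulus*, the simplest
reading of "during sinus rhythm". Self-sustainment is operationalized as:
any -40 mV upstroke more than 50 ms after the last scheduled stimulus,
still present in the final 250 ms of the observation window. Desk-scale
windows default to 2 s (sustainment) and 3 s (analysis), config-scalable to
the clinical-scale 10 s / 8 s; the logic is window-size independent.

For sheet experiments, `cross_field_s2()` induces a single spiral
deterministically: a two-beat S1 train (CL 330 ms) of plane waves - the
rate-dependent APD shortening keeps the first reentrant rotation short
enough to fit the sheet - then a lower-left-quadrant S2 timed
automatically 10 ms after the sheet centre repolarizes below -60 mV. The
auto-timing removes the hand-tuned S1-S2 interval a fixed delay would need
at each resolution; the 10 ms margin gives the S2 wavefront a rim of
recovered tissue, which is what lets the broken end curl rather than
block outright (with no margin the rotor forms but drifts off the sheet
within ~1.5 s).

At desk scale the PV burst protocol on the synthetic fibrotic LA
reproduces repetitive conduction block at the PV base (the LA body follows
only a subset of the five burst beats) but not sustained reentry: the
circuits available around the synthetic ostia are shorter than the
remodeled refractory wavelength, a size effect of the reduced geometry.
Reentry experiments therefore use cross-field induction, where the
circuit is functional rather than anatomical.

# Phase mapping

Phase is `atan2(H[v], v)` of the mean-subtracted voltage over the whole
analysis window (the simplest stationary choice for sustained AF), via the
FFT analytic signal; nodes with < 1 mV excursion are masked. PSs are
elements whose wrapped phase differences around the (consistently oriented)
vertices sum to +/- 2 pi; the detection threshold is |sum| > pi, i.e. the
nearest multiple of 2 pi is +/- 2 pi, robust to discretization noise.
Tracking is greedy nearest-pair matching with equal chirality within 5 mm
per 1 ms frame (the cited tracking threshold is unpublished; 5 mm is far
above per-frame meander and below inter-rotor distances). Trajectories
above 120 ms are rotors. Density maps accumulate per-element occurrence
counts, smooth by inverse-distance-squared within 5 mm (epsilon = one mean
squared edge length bounds the self-term), and normalize to max 1; the
regional PS density is the subdivision *mean* of the smoothed map,
normalized across subdivisions (the mean-vs-max choice is exposed).

# Ablation planning

* **PVI / roof / mitral**: annular bands around the ostia (verified by
  graph disconnection of sleeve from body on the node-sharing adjacency),
  and geodesic bands (Dijkstra shortest path, rasterized at >= one element
  width) between rings or to the mitral boundary.
* **PS-guided shapes**: circle, perforated circle, line, cross at
  0.5-1.5 cm diameter/length, 2 mm band width (clinical lesion diameter;
  the source specifies shapes only by diameter/length). Perforations
  default to 4 symmetric 2 mm gaps - wide enough for wavefront penetration
  at atrial wavelengths, narrow enough to anchor rotors; both counts are
  config-exposed since the source leaves the perforation layout
  unspecified. Placement is the density-map maximum within a subdivision
  (ties to lowest element index; all-zero maps fall back to the
  subdivision centroid with a warning).
* **Streamlining**: seeds evenly spaced *by arc length* along the
  isochrone 10 ms after the earliest LA activation (arc length rather than
  LAT spacing - the evenness convention is not stated in the source), then
  first-order advance in 0.5 mm steps along the normalized LAT gradient
  (barycentric per-triangle gradients) until the mitral boundary; plateaus
  continue along the last direction and are logged. Lesions apply
  instantaneously at the planned RFA time, matching the source's own
  stated limitation.

# Outcomes and statistics

Post-ablation recordings classify as `sinus` (no self-activation in the
terminal second), `AT` (persistent activity, time-median concurrent rotor
count exactly 1, cycle-length coefficient of variation < 10%) or `pAF`.
The AT operationalization is this package's; the source defines AT
conceptually as "a single rotor", and both thresholds are arguments.
Success (for correlation) maps sinus-or-AT to 1. Pearson correlations use
the two-sided t test on n - 2 degrees of freedom, with zero-variance
vectors flagged and rendered as dashes, and no multiple-testing correction
- deliberately mirroring the source analysis.

# Problem sizes, tolerances and what the tests show

The suite and acceptance script run on: the 0.5 mm 50 x 50 mm sheet
(13k nodes) for the rotor cycle-length measurement (>= 2 s of reentry,
dt 20-25 us); the 0.5 mm synthetic LA (36k edges) for fibrosis
calibration; 0.25 mm strips for CV refinement checks; 1 mm meshes for
everything structural. These sizes were chosen so each analysis is a
minutes-scale computation; every algorithm is resolution-independent and
scales to the source's 333 um with configuration changes only.

Key numerical tolerances: achieved LGE densities +/- 0.02; calibration
+/- 50 um; CV vs a 0.1 mm 1D cable within 10%; anisotropy ratio vs
sqrt(sigma_l / sigma_t) within 15% at 0.25 mm (transverse propagation at
coarser grids suffers the usual numerical slowing); dt-refinement changes
APD90 by < 1 ms and snapshots by < 0.5 mV RMS.

Passing tests show the *mechanisms* are faithful - 4:1 fiber-weighted
selection, 670 um clustering, PV < LA APD ordering, conduction block and
reentry on the remodeled substrate, exact PS winding detection, lesion
connectivity semantics, lane monotonicity of streamlining - not that any
patient-specific number of the original anatomy is reproduced. The rotor
cycle length of the desk-scale spiral (~ 203 ms at 0.5 mm) lands near the
clinical 185 +/- 4 ms fibrillatory rate because it is dominated by the
remodeled ionic model, which is shared; the residual gap reflects the
geometry, resolution-dependent conduction slowing and the absent regional
repolarization gradients. The desk-scale reentry carries a median of two
concurrent phase singularities (clinically: 2 +/- 1 rotors). With the
sinus surrogate in the sheet corner, the streamlining scan (analysis
step 5) reproduces the 4-vs-5-line contrast: four lines leave the rotor
in fibrillation, five or more terminate it, and the same experiment shows
the shape contrast - a perforated circle or line 1.5 cm at the PS-density
maximum terminates the rotor, the solid circle anchors it instead, and a
lesion placed in the lowest-density subdivision fails. The threshold
itself depends on the lane geometry (a mid-edge sinus site yields lanes
that terminate the rotor already at two lines), which is itself a finding
the clinical-scale study implies: what matters is lane width at the
rotor, not line count per se.

# Known limitations

Monolayer default (bilayer coupling exists but is unexercised in the
drivers); no mechanical contraction; no electrograms or dominant-frequency
mapping; the flat-sheet posterior/anterior split approximates the
figure-only subdivision boundaries of the source; clinical-scale windows
(10 s sustainment, 8 s analysis) are config-reachable but not exercised in
tests for runtime reasons.
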