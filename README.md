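# atrialab

An in-silico laboratory for persistent atrial fibrillation (pAF) and
virtual radiofrequency ablation (RFA) in the left atrium (LA).

Catheter ablation by pulmonary-vein isolation (PVI) often fails in
persistent AF, where reentrant spiral waves (rotors) live far from the
veins in electrically and structurally remodeled tissue. Testing new
lesion strategies in patients is unsafe, so they are evaluated in
computational models: simulate fibrillation on a fibrotic atrium, map the
rotors' phase singularities (PSs), apply candidate lesion sets virtually,
and score the outcomes. `atrialab` implements that entire workflow as an R
package with a compiled monodomain core, sized so every experiment runs on
a single desktop CPU.

## What is inside

* **Synthetic LA surface** — triangulated sheet (default 50 x 50 mm,
  0.5 mm edges) with four PV ostium holes, a mitral (outer) boundary, a
  fiber field with an abrupt ~90 degree rotation around each ostium, PV
  sleeve / appendage / body region labels and the eight analysis
  subdivisions (posterior 1-4, anterior 5-8).
* **Fibrosis** — per-triangle enhancement-likelihood field matched to
  reference regional densities; stochastic edge selection with weight
  `alpha (4 cos^2 theta + sin^2 theta) L` (parallel edges 4x likelier than
  perpendicular); `alpha` calibrated so the median connected fibrotic
  cluster is 670 um; selected edges split into no-flux discontinuities by
  node duplication.
* **Electrophysiology** — Courtemanche-Ramirez-Nattel human atrial
  kinetics with pAF remodeling (`gNa x2`, `gK1 x0.8`, `Ito x0.5`,
  `IKur x0.5`, `ICaL x0.3`) and PV / appendage variants; Rush-Larsen +
  forward-Euler integration in C++ (dt 20-25 us).
* **Monodomain solver** — P1 finite elements on the surface with
  anisotropic tensor `D_l f f' + D_t (I - f f')`, conductivity calibrated
  to ~70 cm/s longitudinal conduction, 0.001 S/m lesion floor.
* **Protocols** — sinus pacing at 86 bpm, PV burst initiation (5 beats,
  CL 160 ms, coupling 240/400 ms at RSPV/LSPV), cross-field S1-S2 spiral
  induction, sustainment detection.
* **Phase mapping** — Hilbert phase, PS detection by topological charge
  (+/- 2 pi winding per element), greedy trajectory tracking, the 120 ms
  rotor rule, inverse-distance-squared density maps, regional statistics.
* **Ablation planning** — PVI rings with graph-verified isolation,
  geodesic roof/mitral lines, PS-guided circle / perforated circle /
  line / cross lesions (0.5-1.5 cm), and activation-sequence streamlining
  lines traced along the sinus LAT gradient.
* **Outcomes** — sinus / AT / pAF classification and Pearson correlation
  tables between lesion success, PS density and fibrosis density.

## Worked example

Build a fibrotic substrate and calibrate the fibrosis generator:

```r
library(atrialab)

mesh <- build_la_surface(la_geometry_config(edge_length_mm = 0.5, seed = 1))
lge  <- build_lge_map(mesh, seed = 1)
cal  <- calibrate_alpha(mesh, lge, target_median_um = 670,
                        n_seeds = 20, seed = 1)
cal$alpha
#> [1] 0.4893727
cal$achieved_median_um
#> [1] 658.8077
```

The calibrated `alpha = 0.489` makes the median connected fibrotic-edge
cluster 659 um long, within the 670 +/- 50 um target band; selecting with
that alpha marks 9,454 of the 36,236 edges fibrotic in 1,171 clusters,
removes 852 fully-enclosed elements, and `split_edges()` decouples the
clusters while keeping the tissue one conducting component.

Correlate the reference regional densities (fibrosis vs PS density after
right-superior-PV-initiated pAF):

```r
pearson(la_reference_densities$fibrosis, la_reference_densities$ps_rspv)
#> pearson: r = 0.38, p = 0.35, n = 8
```

A weak, non-significant positive correlation: fibrosis density alone does
not predict where rotors live, which is why the lesion planner targets PS
density instead.

The numbered drivers under `analysis/` run the full study: substrate
construction, single-cell APD tables, pAF initiation on the fibrotic LA,
PS mapping of a sustained rotor, the three ablation strategy families, and
the correlation tables. Each writes CSV outputs under `results/`.

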