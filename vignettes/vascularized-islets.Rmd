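---
title: "Modeling oxygen delivery by capillary networks in pancreatic islets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling oxygen delivery by capillary networks in pancreatic islets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletvasc)
```

## The model

Pancreatic islets are clusters of endocrine cells — glucagon-secreting
α-cells, insulin-secreting β-cells and somatostatin-secreting δ-cells —
whose survival depends on oxygen delivered by a dense capillary network.
`isletvasc` simulates that delivery chain on a 1-µm cubic voxel lattice in
five stages:

1. **Islet geometry.** Cells are spheres with typed labels. Architectures
   are loaded from cell tables (x, y, z, type, radius in µm) or synthesized:
   `synthesize_islet()` places cells uniformly in a ball and relaxes them
   with an overlap-minimizing anneal until no two spheres intersect
   (tangency does not count as an overlap). The environment box is the
   sphere bounding box plus a 30-µm buffer per side, and `rasterize()`
   labels every voxel whose center falls strictly inside a sphere with that
   cell's id; everything else is medium.
2. **Capillary seeding.** Initial capillary centerlines are collision-free
   paths between random endpoints on opposite grid faces, found by greedy
   best-first search (frontier ordered by Euclidean distance to the goal,
   6-connected steps, cells are obstacles). A pool of 100 paths per axis
   (300 total) is generated once per islet; sweeps draw random subsets from
   it so that capillary positions stay fixed across conditions.
3. **Capillary growth.** Each selected path becomes one generalized cell of
   a cellular Potts (Glazier–Graner–Hogeweg) model. The Hamiltonian is the
   usual sum of contact energies over unlike neighboring lattice sites plus
   a quadratic volume penalty on each capillary; Metropolis voxel-copy
   attempts (accept if the energy change is non-positive, else with
   probability `exp(-dH/T)`) let capillaries thicken toward their target
   volume and adapt their shape. Endocrine cells are frozen: attempts that
   would modify them are rejected outright, which realizes the "fixed
   obstacle" assumption exactly and removes any need for a cell volume
   constraint.
4. **Oxygen transport.** The steady state of the diffusion–consumption
   balance `D * laplacian(C) = lambda(x)` is solved with capillary voxels
   clamped at 7.02 µM (30 mmHg at a solubility of 2.34e-4 mol/(mmHg·m³)),
   zero-flux boundaries, and zeroth-order consumption in cell voxels at
   glucose-dependent, type-specific rates.
5. **Viability.** Each cell is classified from the mean oxygen partial
   pressure over its voxels: functional above 10 mmHg, hypoxic between 0.45
   and 10 mmHg, non-viable below 0.45 mmHg; viable = functional + hypoxic.
   Slice morphometrics (capillary diameters by profile lines, vascular
   density) mirror the histological protocol, and a modified sigmoid links
   the viable fraction to capillary count and islet size.

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| `J` (contact energies) | capillary–medium 70, cell–medium 80, capillary–cell 10, capillary–capillary 1000 | adhesion (low J) / repulsion (high J) between entity types, arbitrary energy units |
| `r_c` | 3.5 µm | target capillary radius |
| `lambda_vol` | 1000 | capillary volume-constraint strength |
| `T` | 10 | Metropolis temperature |
| `n_mcs` | 300 | Monte Carlo steps (one step = one attempt per lattice site) |
| `D` | 2.1 µm²/ms | oxygen diffusion coefficient in islet tissue |
| capillary concentration | 7.02 µM (30 mmHg) | Dirichlet clamp at capillary voxels |
| consumption (6 mM glucose) | α 0.1313, β 0.1810, δ 0.1170 µM/ms | zeroth-order uptake per cell voxel |
| consumption (20 mM glucose) | α 0.2040, β 0.4850, δ 0.2450 µM/ms | raised uptake under stimulation |
| thresholds | 10 / 0.45 mmHg | functional / viability class boundaries |

The low capillary–cell contact energy makes capillaries strongly adhesive
to endocrine cells, so grown capillaries hug cell surfaces; the prohibitive
capillary–capillary energy prevents distinct capillaries from merging.

## Design choices on open points

Several modeling details are not determined by the published description;
the package fixes them as follows.

**Capillary target volume.** The reference parameter table prints the
target volume as `2 * pi * r_c^2 * L_c0`, twice the volume of a cylinder of
radius `r_c`. A capillary holding twice the cylinder volume over its length
equilibrates at a cross-section of `2 pi r_c^2`, i.e. a diameter of
`sqrt(2) * 7 ≈ 9.9` µm — inconsistent with the measured simulated diameters
(6.44 ± 1.69 µm in human models) reported alongside. The geometric cylinder
volume `pi * r_c^2 * L_c0` reproduces those measurements, so it is the
pipeline default (`cpm_config(volume_mode = "cylinder")`); the printed
formula remains available as `volume_mode = "as_printed"` and in
`target_volume()`.

**Capillary length `L_c0`.** The capillary length that sets the target
volume is described as "calculated from the islet size", and the package
takes it to be the grid dimension along the path's axis
(`L_c0_mode = "axis_dim"`). The alternative — each path's own voxel count —
triples capillary volumes, because 6-connected best-first paths between
random points on opposite faces are Manhattan-inflated (≥ 1.67× the grid
dimension on average, more around obstacles), and visibly breaks the
diameter and density validation.

**Pathfinding connectivity.** Path steps use 6-connectivity (face
neighbors) with first-in-first-out tie-breaking among equal-heuristic
frontier nodes and a fixed neighbor order (+x, −x, +y, −y, +z, −z), so
paths are reproducible; 26-connectivity is available
(`connectivity = 26`), and both produce morphometrics within the reported
spreads at reduced scale.

**Boundary-energy neighborhood.** Interface energies are summed over the
18-neighbor (2nd order) shell, conventional in three-dimensional Potts
simulations; copy attempts pair a site with one of its 6 face neighbors.
Sites outside the lattice contribute no interface energy, and an energy
change of exactly zero is always accepted (Metropolis convention).

**Consumption order.** The transport equation is printed with a
first-order `lambda * PO2` sink, but the consumption table's units (µM/ms)
are a rate, not a rate constant; consumption is therefore zeroth-order by
default — constant uptake wherever oxygen is present, clamped so it never
drives the concentration negative — matching the units and the standard
formulation of islet oxygen-consumption models. A first-order mode
(`consumption_order = "first"`) is kept for sensitivity analysis.

**Vascular density mask.** The histological protocol normalizes vessel
area by a manually outlined islet section that fills the field of view.
The published simulated densities rise by ~0.055–0.059 percentage points
per capillary, which equals total capillary volume normalized by the whole
grid cross-section; a tight morphological mask of the cell+capillary union
gives values several-fold higher, because the adhesive capillaries
concentrate inside the islet. `vascular_density()` therefore defaults to
whole-slice normalization (`mask_rule = "environment"`) and also provides
the tight-mask surrogate (`mask_rule = "closing"`, a 5-µm disc closing);
reports should state the rule used.

**Diameter measurement.** Cross-sections are connected components of one
capillary label in the middle z slice; a profile line through the
component centroid at a random orientation yields the wall-to-wall chord.
Components touching the slice border are skipped, as are fragments smaller
than 13 µm² (a lumen under ~4 µm across is below the physiological
capillary caliber and would not be selected as a vessel on a micrograph).

**Sigmoid identifiability.** In the viability model
`V = Vmin + (Vmax − Vmin) / (1 + (C50/Ncap)^nC (N50/Ncells)^nN)`, the pair
(C50, N50) enters only through `K = C50^nC * N50^nN`, so it is identifiable
only up to a one-dimensional ridge. `fit_viability_model()` fits the
identifiable parameterization (Vmin, Vmax, nC, nN, log K) by multi-start
nonlinear least squares (a data-informed start plus 16 Latin-hypercube
draws over the documented bounds) and reports the ridge point with N50 at
the geometric mean islet size of the records; `log_k` is retained for
ridge-independent comparisons. Published parameter sets are one point on
their ridge and reproduce the same surface.

**Packing anneal.** The overlap-minimizing anneal accepts any move that
reduces the overlapping-pair count and other moves with a geometrically
decaying probability (`p0 = 0.5`, decaying to 1e-3 by half the iteration
budget); the best configuration seen is returned, so the count never
increases. Cell selection is biased 9:1 toward cells currently involved in
an overlap — with uniform selection the last few overlaps stall for O(n)
iterations; the fixed point (zero overlaps) is unchanged.

## The synthetic islet generator

`synthesize_islet()` emulates the size and composition statistics of
reconstructed islets: type fractions default to 0.29/0.53/0.18 (α/β/δ) for
human and 0.25/0.75 for mouse (mouse models carry no δ-cells); radii come
from a truncated normal (mean 5.5 µm, sd 0.8 µm, bounds 3.5–8 µm), a
documented stand-in for the unpublished empirical distributions; the
default target diameter requests a nominal cell volume fraction of 0.55.
Two caveats follow from the annealing construction. First, because
perturbations re-draw radii, dense targets select for smaller radii (the
realized mean radius falls to ~4.5 µm and the realized volume fraction
plateaus near 0.33), so synthetic islets are somewhat more porous than
real islet tissue; capillaries can therefore thread the interstitium more
freely than in reconstructed architectures. Second, synthetic islets are
spherical, without the lobes and concavities of real islets. Tests passing
on synthetic islets validate the simulation machinery and its scaling
behavior, not the anatomical detail of any particular reconstructed islet.

## Numerical choices

The oxygen solver is a projected red-black successive over-relaxation on
the discrete steady-state equations: Dirichlet values at capillary voxels,
zero-flux boundaries realized by dropping missing neighbors from the
stencil, and projection at zero realizing the clamped zeroth-order sink.
Convergence requires the largest discrete residual (µM/ms) below `tol`
(default 1e-6) at every non-clamped voxel; voxels pinned at zero satisfy a
one-sided condition (diffusive influx not exceeding the consumption
capacity). The over-relaxation factor defaults to
`2 / (1 + sin(pi / (2 * max(dim))))`. Against the 1-D two-plane slab with
uniform zeroth-order consumption the solver matches the piecewise closed
form (including the dead-core case) to better than 1% of the clamp
concentration.

The Potts evolution keeps incremental energy bookkeeping and audits it
against a full recomputation at checkpoints (tolerance 1e-6 relative); a
run is reported converged when the relative energy change over the last 50
MCS falls below 1e-3. All randomness — placement, radii, endpoints,
Metropolis draws, subsets — flows through R's RNG, so a master seed makes
entire pipelines bit-reproducible.

## Reduced-scale protocol

Full-size reference environments (~3×10⁷ voxels) are feasible but slow on
a single core, so the packaged validation runs at reduced scale: synthetic
human-style islets of a few hundred cells in 120–170 µm environments, with
capillary counts scaled to preserve capillaries per unit cross-sectional
area relative to the mean reference human environment (78,211 µm² mean
face area). At that loading-preserving scale the mid-slice capillary
diameters and vascular density land within the reported spreads, viability
percentages exceed the reported floors, and the capillary-count sweep
(scaled equivalents of 5–300 capillaries over three islet sizes, both
glucose levels) supports the sigmoidal fit. The problem sizes used by the
acceptance script — three 420-cell islets at 300 MCS for morphometrics and
viability, sweep islets of 140/220/340 cells at 100 MCS — are the
package's chosen desk-scale protocol. Two consequences of the reduction
are worth keeping in mind when reading reduced-scale numbers: the scaled
equivalents of the smallest reference counts round to one or two
capillaries, where a single path's placement can move an islet's viable
fraction by ~0.2 (inflating the sweep-fit residuals relative to a
full-scale sweep), and per-islet viability percentages fluctuate more
than at full scale simply because fewer cells and capillaries are
averaged.

## Limitations

Hemodynamics are absent: no blood flow, no intravascular oxygen depletion,
no arteriole/venule hierarchy, no branching or anastomosis — capillaries
are independent face-to-face tracks, as in the source model. The oxygen
clamp idealizes capillaries as inexhaustible sources at venous-range
tension. Hormone secretion and paracrine signaling are out of scope. Mouse
viability-model parameters were never published in table form, so mouse
predictions require a user-supplied fit (`fit_viability_model()` +
`predict_viability(params = ...)`).
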