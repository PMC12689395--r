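# isletvasc

Simulation of oxygen delivery by capillary networks in three-dimensional
pancreatic islet models, and prediction of islet cell viability from the
degree of vascularization.

Pancreatic islets — clusters of glucagon-secreting α-cells,
insulin-secreting β-cells and somatostatin-secreting δ-cells — are among
the most densely vascularized tissues in the body, and their survival
after isolation or transplantation hinges on how much of that capillary
supply is preserved or rebuilt. `isletvasc` is for researchers in islet
physiology, transplantation and tissue engineering who want to ask, *in
silico*: how many capillaries does an islet of a given size need so its
cells stay oxygenated and functional at a given glucose level?

## What it computes

The simulator chains five stages on a 1-µm voxel lattice:

1. **Islet architecture** — endocrine cells as typed spheres, loaded from a
   cell table (`x,y,z,type,radius`) or synthesized by overlap-minimizing
   sphere packing (`synthesize_islet()`), then rasterized.
2. **Capillary seeding** — collision-free centerlines between random points
   on opposite grid faces, by greedy best-first search over the lattice
   with cells as obstacles; 100 paths per axis form a pool from which
   subsets are drawn.
3. **Capillary growth** — a cellular Potts (Glazier–Graner–Hogeweg) model:
   voxel-copy attempts accepted by the Metropolis rule minimize

   `H = Σ_neighbors J(τ_i, τ_j) (1 − δ_{σ_i σ_j}) + Σ_capillaries λ_c (v − V_c)²`

   with frozen endocrine cells, contact energies J(capillary, medium) = 70,
   J(cell, medium) = 80, J(capillary, cell) = 10, J(capillary, capillary)
   = 10³, volume constraint λ_c = 10³ and temperature T = 10.
4. **Oxygen transport** — the steady state of
   `∂C/∂t = D ∇²C − λ(x) + S`, with D = 2.1 µm²/ms, capillary voxels
   clamped at 7.02 µM (30 mmHg), zero-flux boundaries, and zeroth-order
   consumption in cell voxels (e.g. β-cells consume 0.1810 µM/ms at 6 mM
   glucose and 0.4850 µM/ms at 20 mM).
5. **Viability** — cells classified from their mean PO₂: functional
   (> 10 mmHg), hypoxic (0.45–10 mmHg) or non-viable (< 0.45 mmHg);
   viable = functional + hypoxic. Slice morphometrics (profile-line
   capillary diameters, vascular density) mirror the histological
   protocol.

On top of the simulations, a modified sigmoid

`V = V_min + (V_max − V_min) / (1 + (C50/N_cap)^{n_C} (N50/N_cells)^{n_N})`

links the viable fraction to capillary count and islet size;
`fit_viability_model()` fits it to sweep records and
`predict_viability()` evaluates it (bundled human parameter sets for 6 and
20 mM glucose; e.g. C50 = 6.82 capillaries, N50 = 669.16 cells, n_C = 1.92,
n_N = −1.70 at 6 mM).

## Worked example

A small synthetic human islet at a loading equivalent to 100 capillaries
in a full-size islet:

```r
library(isletvasc)

arch <- synthesize_islet(n_cells = 150, species = "human", seed = 42)
print(arch)
#> Islet architecture (human): 150 cells (alpha 49, beta 68, delta 33)
#> Environment: 136 x 135 x 132 um (buffer 30 um), overlaps: 0

grid <- rasterize(arch)
pool <- generate_initial_capillaries(grid, n_per_axis = 10, seed = 43)
sub  <- select_capillary_subset(pool,
          capillary_count_equivalent(100, dim(grid)), seed = 44)  # 23 paths
grown <- evolve_capillaries(grid, cpm_config(), seed = 45, paths = sub)

field <- relax_to_steady_state(grown, oxygen_params("G6"))
print(field)
#> Oxygen field: converged after 800 sweeps (max residual 8.63e-07 uM/ms)
#>   concentration range 3.676-7.020 uM (15.71-30.00 mmHg)

report <- summarize_viability(cell_oxygen_summary(grown, field), grown, field)
print(report)
#> Viability report (150 cells): 100.0% functional, 0.0% hypoxic, 0.0% non-viable (viable 100.0%)
#>   mean medium oxygen: 6.782 uM (28.98 mmHg)

slice <- extract_mid_slice(grown)
vascular_density(slice)                       # 3.48 %
mean(measure_capillary_diameters(slice, 100)) # 6.24 um
```

At this loading every cell sits within the oxygen penetration depth of a
capillary, so the whole islet is functional at 6 mM glucose; the mid-slice
morphometrics (≈6 µm capillary diameters, a few percent vascular density)
are in the physiological range for islet microvasculature. The same
question answered from the fitted sigmoid, without a simulation:

```r
predict_viability(n_cap = 100, n_cells = 1500, glucose = "G20")
#> Predicted viable proportion: 0.965
#>   inputs: 100 capillaries, 1500 cells, G20, human (parameters: published)
```

`run_pipeline()` wraps the whole chain (with artifact export and a
manifest); `sweep_capillary_counts()` runs islet × capillary-count ×
glucose sweeps whose records feed `fit_viability_model()`. A thin
command-line wrapper lives at `inst/scripts/isletsim`
(`predict`, `fit`, `run` subcommands).

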