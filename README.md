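# immsort

Curvature-driven lipid sorting analysis for mitochondrial inner-membrane
(IMM) cristae models.

## The problem

Cristae — the tubular invaginations of the inner mitochondrial membrane —
expose lipids to mean curvatures of order ±0.1 nm⁻¹ and, at the neck where a
tube meets a flat sheet, to negative Gaussian curvature. Cone-shaped lipids
such as phosphatidylethanolamine (PE) and cardiolipin (CDL) preferentially
partition into regions whose curvature matches their spontaneous curvature
H₀, and quantifying that sorting requires (i) a geometry with biologically
realistic curvature scales, (ii) per-leaflet curvature fields, and (iii)
careful compartmental statistics with honest error bars.

`immsort` provides the full analysis chain for coarse-grained simulations of
a parametric crista — a cylinder of mid-surface radius `r_cyl` joined to two
flat sheets through tangent-continuous quarter-torus junctions, held in
shape by lattices of repulsive "dummy" scaffold particles — plus an
equilibrium Monte Carlo generator that produces curvature-coupled sorting
trajectories with the same statistical structure, so every stage of the
pipeline is testable at desk scale.

## What it computes

- **Geometry** (`imm_geometry`, `leaflet_surface`, `dummy_lattice`,
  `analytic_curvature`): leaflet surfaces offset ±t/2 from the mid-surface,
  the flat/junction/cylinder region partition in polar (ρ, z) coordinates
  (ρ = √(x² + y²)), closed-form mean and Gaussian curvature per leaflet, and
  dummy-particle shells bracketing the bilayer.
- **Frame I/O** (`read_frames`, `write_frames`, `assign_leaflets`): GRO, PDB
  and tabular frame formats; leaflet and region labels from headgroup-marker
  beads (phosphate midpoint for cardiolipin).
- **Curvature estimation** (`estimate_curvature`): per-vertex H and K from
  local quadric Monge patches over k nearest neighbours,
  H = (C₁ + C₂)/2, K = C₁·C₂, signed against the leaflet-outward normal.
- **Partitioning statistics** (`count_by_compartment`, `lipid_fraction`,
  `enrichment_factor`, `block_error`, `running_mean`,
  `spatial_percent_change_map`): per-compartment lipid fractions
  LFᵢ = nᵢ/Σnᵢ and the enrichment/depletion factor

      F = (⟨LF⟩_(ta→tb) − LF_(t=0)) · 100

  with block-averaged errors (80 ns blocks), 40 ns running means, and
  thresholded (ρ, z) percent-change maps (1.5 percentage-point significance
  threshold).
- **Force sensing** (`restraint_forces`, `mean_dummy_force`, `force_map`):
  dummy particles as force sensors, Fᵢⁿ = −k_pr(aᵢⁿ − Aᵢⁿ), in restrained
  and frozen modes, with polar force maps.
- **Flat-bilayer observables** (`bilayer_thickness`, `area_per_lipid`,
  `order_parameter_p2`, `splay_angle`, `pressure_profile`): the structural
  audit used to establish that the scaffold does not perturb the membrane,
  including the lateral pressure profile π(z) = P_L(z) − P_N(z).
- **Correlation** (`enrichment_curvature_correlation`): Pearson r between
  compartment enrichment factors and compartment-mean H or K over the six
  (leaflet × region) compartments.
- **Synthetic generator** (`sorting_model`, `mc_sort`, `null_system`,
  `wall_toy_sim`): Kawasaki exchange Monte Carlo with per-site Helfrich-like
  energies E_s = ½ κ_s a_s (H − H₀ₛ)² − κ̄_s a_s K, a label-only null
  control, and an overdamped dummy-wall toy with known applied loads.
- **Pipeline** (`run_pipeline`): YAML-configured end-to-end run with a
  manifest; bit-reproducible under a fixed seed.

## Worked example

```r
library(immsort)

geom <- imm_geometry()                  # 10 nm cylinder radius crista
sp <- default_sorting_species()         # POPC/POPE/DOPE/CDL2/CDL1 presets
sp <- sp[sp$name %in% c("POPC", "CDL2"), ]
sp$fraction <- c(0.8, 0.2)

run <- mc_sort(sorting_model(geom, sp), n_sweeps = 1500,
               record_every = 10, seed = 1)
enr <- enrichment_factor(lipid_fraction(count_by_compartment(run)))
subset(enr, species == "CDL2")
#>  leaflet   region species      F block_error
#>    inner     flat    CDL2 -0.291       0.034
#>    inner junction    CDL2 -1.223       0.052
#>    inner cylinder    CDL2  3.090       0.067
#>    outer     flat    CDL2 -0.017       0.064
#>    outer junction    CDL2  2.282       0.074
#>    outer cylinder    CDL2 -2.366       0.059
```

The cardiolipin-like tracer (spontaneous curvature −0.25 nm⁻¹) enriches by
about +3.1 percentage points in the inner-leaflet cylinder (mean curvature
−0.0625 nm⁻¹) and +2.3 in the outer-leaflet junction, and depletes from the
outer cylinder (+0.042 nm⁻¹) — the sorting pattern expected for a
negative-curvature-preferring lipid, with block errors far below the
signals. Correlating these six factors with compartment curvature:

```r
curv <- region_curvature_summary(cbind(run$model$sites[, c("leaflet", "region")],
                                       H = run$model$sites$H,
                                       K = run$model$sites$K))
enrichment_curvature_correlation(enr, curv, species = "CDL2")
#>   species  r_mean r_gauss n
#> 1    CDL2 -0.9967 -0.1755 6
```

The strong negative correlation with mean curvature and the weaker negative
correlation with Gaussian curvature show mean-curvature sensing dominating.

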