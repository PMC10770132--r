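---
title: "Curvature-driven lipid sorting on cristae membrane models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curvature-driven lipid sorting on cristae membrane models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immsort)
```

## The model system

`immsort` analyses lipid partitioning on a parametric model of an inner
mitochondrial membrane crista: a bilayer tube of mid-surface radius
`r_cyl` and axial length `l_cylinder`, joined at each end to a flat square
sheet of edge `l_flat` through a quarter-torus junction of tube radius
`r_junction` that is tangent-continuous with both the tube and the sheet.
The defaults (`r_cyl = 100` Å, `r_junction = 100` Å, `l_cylinder = 300` Å,
`l_flat = 560` Å) put the surface at the curvature scale of real cristae
(tens of nanometres). The tube axis is `z`; because everything is
axisymmetric, analyses work in polar coordinates `(rho, z)` with
`rho = sqrt(x^2 + y^2)`.

The surface splits into three curvature regions — `cylinder`, `junction`
and `flat` — and two leaflets. The inner leaflet faces the crista lumen
(the tube interior and the far side of each sheet); the outer leaflet faces
the matrix. Offsetting the mid-surface by half the bilayer thickness
(`t/2 = 20` Å by default) along the local normal gives each leaflet a
closed-form curvature field with the characteristic sign pattern:

| leaflet | flat | junction | cylinder |
|---|---|---|---|
| outer | H = 0, K = 0 | H < 0, K < 0 | H > 0, K = 0 |
| inner | H = 0, K = 0 | H ≈ 0⁺, K < 0 | H < 0, K = 0 |

with H signed against the leaflet-outward normal (a cylinder seen from
outside scores `H = +1/(2R)`). Only the junction carries Gaussian
curvature, which is what lets the package separate mean-curvature from
Gaussian-curvature sensing.

Two lattices of "dummy" scaffold particles bracket the bilayer at
`dummy_gap/2 = 25` Å from the mid-surface with 5 Å lateral spacing. In the
simulations this package post-processes, such particles hold the membrane
in shape via a purely repulsive Lennard-Jones interaction (C12 = 0.0258
kJ nm¹² mol⁻¹, C6 = 0, carried as metadata); here they serve as force
sensors and as the export target for system building.

### Geometry conventions

- The cylinder mid-plane is at `z = 0`; flat sheets at
  `z = ±(l_cylinder/2 + r_junction)`. `l_cylinder` is the cylinder-proper
  extent; a switch (`l_cylinder_includes_junctions`) supports the
  alternative convention in which the quoted length spans the junction arcs
  too, since build tools are ambiguous on this point.
- Region boundaries are half-open with ties to the more curved region: the
  cylinder owns the cylinder–junction seam (`|z| = l_cylinder/2`), the
  junction owns the junction–flat seam (`rho = r_cyl + r_junction`). This
  makes assignment deterministic and order-independent.
- The leaflet offset `t/2` defaults to 20 Å, half a typical coarse-grained
  bilayer thickness; it is configurable because per-leaflet curvature
  depends on it and no single value suits every force field.
- Lengths are Å internally; curvature is reported in nm⁻¹ (H) and nm⁻²
  (K), forces in kJ mol⁻¹ nm⁻¹. Conversions are centralised.

## Leaflet labelling

All per-lipid logic anchors on a headgroup-marker bead — the phosphate
bead, or the midpoint of the two phosphate beads for cardiolipin (which
has no single phosphate). The leaflet is the sign of the signed distance
from the marker to the mid-surface along the local normal; markers farther
than the bilayer thickness from the mid-surface are flagged unassigned
rather than silently binned.

## Curvature estimation from point clouds

`estimate_curvature()` reconstructs per-vertex curvature directly from the
headgroup positions of one leaflet: a local frame from the covariance of
the `k_neighbors = 12` nearest neighbours, a quadratic Monge patch
`h(u,v) = (a u² + 2b uv + c v²)/2 + d u + e v + f` fitted by least squares,
and H, K from the fundamental forms of the fit. Design choices:

- **Vertices are the input points** (no remeshing), so curvature is
  available per lipid for sorting correlations.
- **Quadratic, not cubic, patches with k = 12**: stable at coarse-grained
  headgroup densities (~0.8 nm spacing); cubic terms are unidentifiable at
  12 points and inflate variance.
- **Orientation**: normals are matched to the cristae geometry when a
  `geom_hint` is supplied, else oriented outward from the cloud centroid
  (adequate for convex clouds; ambiguous on the inner rim of a torus,
  which the tests acknowledge by comparing |H| there).
- **Outliers** are vertices whose fit residual exceeds 5× the median
  residual, with an absolute floor of a tenth of the local patch scale so
  exactly planar neighbourhoods (residual ≈ 0) cannot drag the threshold
  to machine precision. Flagged vertices stay in the output but leave the
  summaries.

Calibration on canonical surfaces at default density: sphere and cylinder
means recover closed forms to well within 5% (H) and 10% (K); a plane with
0.5 Å vertical noise at 8 Å spacing shows a noise floor of median
|H| ≈ 0.024 nm⁻¹ — below the weakest cristae signal (|H| ≈ 0.04 nm⁻¹ in
the junction) but not negligible, which is why region averages over many
vertices, not single-vertex values, enter the correlation analysis.

## Partitioning statistics

For each (leaflet × region) compartment and species, the lipid fraction is
`LF_i = n_i / sum_i n_i` and the enrichment/depletion factor is

`F = (<LF>_(ta→tb) − LF_(t=0)) · 100`

in percentage points, with the baseline taken from the first stored frame
(the build protocol mixes lipids uniformly, so the first frame is the
uniform reference). Errors are block-averaged standard errors with 80 ns
blocks (trailing partial block dropped); time series are smoothed with a
40 ns centred running mean with truncated edges. Within a compartment the
factors sum to zero across species by construction.

Spatial `(rho, z)` maps use 10 Å bins (fine enough to resolve a 100 Å
junction), report per-bin local composition percentage minus the global
bulk percentage at `t = 0`, and zero out magnitudes below a 1.5
percentage-point significance threshold — the level below which a
label-only control shows only noise. Empty bins are `NA`, distinct from
zero. A `min_occupancy` floor can additionally mask undersampled sliver
bins (a desk-scale concern: a bin holding a handful of lattice sites has
binomial noise above the display threshold no matter how long the run).
Local-total normalisation (rather than global) is used because it
reproduces the canonical worked example: a 20% bulk species rising to a
localized 25% scores +5.

The two junctions and two flat sheets are pooled into one compartment each
(the geometry is mirror-symmetric), giving six compartments per system.
Frames are weighted uniformly.

## Force sensing

Restrained dummy particles report the force they transmit as the restraint
reaction `F_i^n = −k_pr (a_i^n − A_i^n)` per axis (k_pr = 1000
kJ mol⁻¹ nm⁻² by default); frozen particles report their recorded
interaction forces directly. Maps and summaries use the magnitude of the
time-mean force vector, not the mean of magnitudes, so thermal noise
cancels and only sustained loads survive — the convention that makes
equilibrium systems read near zero. An alarm level of 10 kJ mol⁻¹ nm⁻¹
marks the regime where the scaffold would start perturbing the bilayer.

The wall-toy generator validates the sensing identity: overdamped pusher
particles driven by a constant load `F_app` press through a harmonic
contact onto restrained (or frozen) wall particles. At stationarity the
mean sensed force equals the applied load per particle and lateral
components fluctuate about zero. The reported standard error is the
maximum of a doubling block-size scan (64 down to 4 blocks) — the
conservative plateau choice of Flyvbjerg–Petersen block analysis — because
a single arbitrary block length risks understating correlated noise.

## The synthetic sorting generator

The generator exists to give the analysis stack inputs with the
statistical structure it assumes, at desk scale, with known ground truth.
It is an equilibrium lattice model, not a molecular dynamics surrogate:

- Sites are a fixed quasi-uniform sampling of both leaflet surfaces
  (default 8 Å spacing, ≈26,000 sites on the default geometry), each
  carrying its analytic H and K.
- A lipid of species s on site x contributes
  `E_s(x) = ½ κ_s a_s (H(x) − H0_s)² − κ̄_s a_s K(x)` in units of kT —
  a per-lipid Helfrich-like bending penalty plus an optional Gaussian
  coupling. Species labels exchange between random same-leaflet site pairs
  (Kawasaki moves) under Metropolis acceptance, so composition is
  conserved exactly and the stationary distribution is the canonical
  ensemble of the site energies (verified against exact enumeration on an
  8-site toy).
- Default species presets: κ = 12 kT, molecular areas 0.64 nm² (1.20 nm²
  for the cardiolipin-like species), spontaneous curvatures 0, −0.10,
  −0.15, −0.25, −0.35 nm⁻¹ for POPC-, POPE-, DOPE-, CDL⁻²- and CDL⁻¹-like
  species. These are generator conventions chosen once to produce weak,
  few-percent sorting signals of the kind the analysis must resolve; they
  are not force-field parameters.
- One sweep (N attempted exchanges) maps to 0.8 pseudo-ns, so the 40 ns
  running window and 80 ns blocks are exercised meaningfully; a default
  run of 1500 sweeps spans 1.2 pseudo-μs with 150 stored frames.
- Initial configurations are uniformly mixed **stratified by compartment**:
  within each (leaflet × region) group the species counts follow the bulk
  fractions exactly (largest-remainder rounding) before shuffling. A fully
  random initial assignment would put ~0.8 percentage points of binomial
  noise into the `t = 0` baseline of every compartment at these lattice
  sizes, and F would measure initialisation luck as much as sorting; the
  stratified start keeps the baseline at bulk so F measures dynamics.
  Runs are bit-reproducible under a fixed seed.

The label-only null control (`null_system()`) relabels 20% of a
single-species system as `TEST` without changing any energy — the
convergence control: any apparent TEST enrichment is pure sampling noise,
and in practice its maximum significant |F| stays below a tenth of a
percentage point.

### What the generator does and does not emulate

It reproduces: two leaflets with distinct curvature fields, several
species with distinct curvature preferences, composition-conserving
exchange dynamics with a tunable pseudo-time scale, equilibrium
fluctuations with realistic block-error structure, a null control, and
known applied loads in the wall toy. It does **not** reproduce: molecular
interactions (electrostatics, hydrogen bonding, lipid–lipid enthalpy),
membrane shape fluctuations (sites are fixed), lipid flip-flop between
leaflets, aggregation, or absolute enrichment magnitudes of any particular
force field. Passing tests therefore certify the *analysis pipeline* —
signs, orderings, error calibration, recovery of known couplings — not
quantitative agreement with any molecular system.

Two consequences are worth knowing. First, in a five-species mixture the
strongest curvature-coupled species crowd the scarce inner-cylinder sites
and scramble the enrichment ranking of the weaker ones; ranking
experiments therefore use binary host/minor systems (one minor species at
20% in a POPC-like host), which is also how such rankings are established
in practice. Second, enrichment grows as the cylinder tightens
(15 → 10 → 5 nm radius) because the inner-leaflet cylinder curvature moves
toward the tracers' spontaneous curvatures — the geometric response the
compartmental analysis must detect.

## Numerical choices and degenerate inputs

- Lateral pressure profiles use the standard `P_L = −(σxx + σyy)/2`;
  a compatibility switch (`convention = "unhalved"`) reproduces the
  variant without the ½ that appears in parts of the membrane literature.
  Bilayer thickness is phosphate-to-phosphate.
- `block_error()` refuses windows shorter than two blocks rather than
  returning an optimistic number; empty compartments yield masked (`NaN`)
  fractions, never zeros.
- Rank-deficient curvature fits (collinear neighbourhoods) are flagged,
  not dropped; zero-length bonds are excluded from order parameters with a
  warning; zero-variance inputs make the Pearson correlation `NA` with a
  warning instead of an arbitrary value.
- Problem sizes in the shipped tests are chosen for desk-scale runs: point
  clouds of 2,000–8,000 vertices for the curvature oracles, the ≈26,000
  site default lattice with 1,500-sweep runs for sorting experiments
  (20 seeds for the ranking study), and 20,000-step wall-toy runs with 25
  particles per load.

## Known limitations

- The curvature estimator's centroid orientation rule is ambiguous on
  surfaces that fold around their centroid (inner torus rim); supply a
  geometry hint where available.
- Periodic-boundary unwrapping is limited to structures whole within the
  box; trajectories with broken molecules should be made whole upstream.
- The six-point enrichment–curvature correlation is statistically fragile
  by construction (six compartments); the package therefore also offers a
  frame bootstrap interval, reported separately from the point estimate,
  and no significance test is attached to the six-point r.
- XTC/TRR binary trajectory formats are out of scope; convert to GRO, PDB
  or frame tables upstream.
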