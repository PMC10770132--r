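Package: immsort
Title: Curvature-Driven Lipid Sorting Analysis for Mitochondrial Inner
    Membrane Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing lipid sorting on curved bilayer models of
    mitochondrial inner-membrane (IMM) cristae. Provides a parametric
    cylinder/junction/flat cristae geometry with dummy-particle scaffold
    lattices and an analytic curvature oracle, coordinate-frame input/output
    (GRO, PDB and a tabular frame format) with leaflet and region labelling,
    point-cloud estimation of mean and Gaussian leaflet curvature via local
    quadric fits, compartmental lipid-fraction and enrichment/depletion
    statistics with block-averaged errors and thresholded spatial maps,
    dummy-particle force sensing in restrained and frozen modes, flat-bilayer
    structural observables (thickness, area per lipid, bond order parameter,
    splay angle, lateral pressure profiles), enrichment-curvature correlation
    summaries, and an equilibrium Metropolis exchange Monte Carlo generator
    of curvature-coupled lipid-sorting trajectories with a label-only null
    control and a dummy-wall force-sensor toy model.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
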