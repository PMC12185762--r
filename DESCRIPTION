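Package: epivertex
Title: Vertex-Model Mechanics of Ciliated Epithelia and Macropinocytosis
    Event Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a planar vertex model of a proliferating epithelial
    monolayer containing stiff, non-dividing multiciliated cells (MCCs).
    Mesh topology is encoded by signed edge-vertex and cell-edge incidence
    matrices and cell mechanics follow a logarithmic force-strain law with
    a per-cell stiffness prefactor. Provides the growth protocol
    (hexagonal seed, exclusion-radius MCC placement, division arrest,
    relaxation to equilibrium), per-cell stress measures (effective
    pressure, cortical tension, shear) with decile-enrichment statistics
    around MCCs, geometry-based relative junction-tension inference at
    triple junctions with N1-N4 ring classification, estimators for
    macropinocytosis event tables and apical-area tracks, and
    synthetic-data generators producing all analysis inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    MASS,
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
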