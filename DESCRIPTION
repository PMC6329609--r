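Package: segwave
Type: Package
Title: Gene-Network Simulators for Threshold-Based and Speed-Regulated
    Axial Patterning
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Deterministic simulators for gene regulatory networks that
    partition a one-dimensional field of cells into ordered fate domains
    under a posterior morphogen gradient, as in insect anterior-posterior
    segmentation. Implements four network families -- French Flag
    (morphogen-threshold readout), French Flag with a Timer Gene, and two
    realizations of threshold-free Speed Regulation (dynamic/static module
    switching and joint modulation of production and decay) -- on static
    and posteriorly elongating tissues. Provides kymograph containers built
    on SummarizedExperiment, in-silico perturbations (transient re-induction
    of the leading gene, RNAi, posteriorized morphogen), pattern analytics
    (fate maps, boundaries, steady-state and kinematic-wave diagnostics, a
    reset assay discriminating threshold-based from threshold-free
    patterning), and region-based scoring of simulated embryo ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllGenerics.R'
    'AllClasses.R'
    'networks.R'
    'morphogen.R'
    'simulate.R'
    'kymograph.R'
    'perturbations.R'
    'analysis.R'
    'scoring.R'
    'config.R'
    'presets.R'
    'segwave-package.R'
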