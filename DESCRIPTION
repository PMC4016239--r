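Package: pseudoflux
Title: Near-Optimal Flux Space Objectives for Constraint-Based Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based analysis of genome-scale metabolic models with an
    objective function that predicts mutant flux distributions as the minimum
    Euclidean distance between the mutant's feasible flux polytope and the
    wild type's near-optimal growth region. Provides flux balance analysis
    (FBA) with a parsimonious 1-norm secondary objective, minimization of
    metabolic adjustment (MOMA), quadratic and second-order-cone formulations
    of the polytope-to-polytope distance objective, flux variability analysis,
    artificially-centered hit-and-run sampling of the near-optimal region, and
    downstream analyses: lethality calls, carbon-fate partitioning, sensitivity
    scans, growth-threshold sweeps, and dependent-correlation comparisons.
    Reads and writes SBML Level 3 (fbc) and COBRA-style JSON models; includes a
    synthetic toy-network generator with analytically known optima for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    quadprog,
    nloptr,
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
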