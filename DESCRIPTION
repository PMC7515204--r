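Package: mitoredox
Title: Kinetic Modeling of Hydrogen Peroxide Dynamics in Mitochondria
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A mass-action kinetic model of the hydrogen peroxide reaction
    network in the mitochondrial matrix of HeLa cells: 30 reactions over 28
    chemical species spanning the thioredoxin/peroxiredoxin and
    glutathione/glutathione-peroxidase/glutaredoxin antioxidant systems,
    including peroxiredoxin-3 hyperoxidation and its sulfiredoxin-mediated
    repair. Provides stiff-ODE integration with steady-state detection and
    fixed-point refinement, Monte Carlo uncertainty analysis over the feasible
    peroxiredoxin-3 pool, local finite-difference sensitivity analysis,
    perturbation sweeps with a collapse-threshold bisection, an efflux-refined
    Monte Carlo, unit bridges between proteomic copy numbers and
    per-mitochondrion concentrations, and a synthetic redox-Western
    densitometry generator with the associated ANOVA/Tukey comparison stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
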