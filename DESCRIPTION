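Package: tfcircuit
Title: Gradient-Based Design of Transcription-Factor Genetic Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and gradient-based optimization of transcription-factor
    (TF) genetic circuits. Models mRNA/protein dynamics with a thermodynamic
    multi-TF promoter-occupancy activation function, integrates the system as
    deterministic ODEs or as chemical-noise stochastic differential equations
    (Euler-Maruyama with abundance-scaled noise), and fits biologically bounded
    parameters by backpropagating a circadian trajectory loss through the
    unrolled solver with the Adam optimizer and curriculum lengthening of the
    fitting window. Includes random telegraph light entrainment, ensemble
    evaluation of entry-time deviations, and TF input-output logic surfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'tfcircuit-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'bounds.R'
    'params.R'
    'regulation.R'
    'dynamics.R'
    'objective.R'
    'optimize.R'
    'evaluate.R'
    'cli.R'
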