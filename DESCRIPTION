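Package: flipkin
Title: Transient Kinetics of Enzyme-Catalyzed Nucleotide Flipping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-action modelling and transient-kinetic analysis of lesion
    recognition by DNA glycosylases. Simulates a minimal search/flip/excise
    mechanism deterministically and stochastically, generates realistic
    synthetic stopped-flow fluorescence and gel-based observables (association
    in two sequence contexts, double-mixing chase, tight-binding titrations,
    single-turnover excision, pulse-chase partitioning, competition series),
    extracts observed rate constants by multi-exponential and nonlinear fits,
    fits the full mechanism globally across mixing regimes, and compiles
    microscopic rate and equilibrium constants (flipping equilibria,
    commitment to catalysis, fold changes) for enzyme variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
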