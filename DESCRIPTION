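Package: actoring
Title: Mechanochemical Simulation of Actomyosin Ring and Cluster Formation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic mechanochemical simulation of confined actomyosin
    networks. Filament treadmilling chemistry (polymerization,
    depolymerization, formin-mediated nucleation, filament destruction,
    motor and crosslinker binding, myosin walking) is propagated with the
    Next Reaction Method and coupled to semiflexible-polymer mechanics
    (stretching, bending, excluded volume, harmonic motor and linker
    springs, exponential boundary repulsion) through force-dependent
    reaction rates (Brownian ratchet, slip and catch bonds, Hill
    force-velocity). Includes morphology quantification (radial density
    statistics, normalized radial median, grid-based cluster detection,
    treadmilling and turnover rates, mechanical energy), quantification of
    TIRF-like intensity images, and synthetic-data generators so every
    analysis stage is testable without running the simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
LinkingTo: Rcpp
RoxygenNote: 7.3.3
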