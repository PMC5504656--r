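Package: tnbcABM
Title: On-Lattice Agent-Based Model of Triple-Negative Breast Cancer Growth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A stochastic 3D cellular-automaton model of triple-negative
    breast cancer growth on a voxel lattice. Tumor cells are autonomous
    agents with a stem/progenitor lineage hierarchy, CCR5-high/low
    migratory phenotypes, contact-driven quiescence, division-limited
    senescence, and geometric hypoxia near a static vessel structure.
    Includes in-silico treatments (pulsed anti-stem-cell dosing and
    continuous CCR5 inhibition), replicate/sweep experiment drivers,
    exponential growth-curve fitting, and 3D tumor morphometrics
    (chord ratio, chord length, moment of inertia, circularity, and
    box-counting fractal dimension of the tumor surface).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
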