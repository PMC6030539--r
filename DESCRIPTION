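Package: juvsus
Title: Evolution of Juvenile Susceptibility in Stage-Structured SIS Host-Parasite Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolution of juvenile susceptibility to
    infectious disease in an age-structured SIS host-parasite model. Juvenile
    susceptibility is linked by a trade-off to either adult reproduction or
    the maturation rate. The package provides the ecological model (forces of
    infection under density- or frequency-dependent transmission, equilibria,
    basic reproduction number), adaptive-dynamics analysis (invasion fitness,
    selection gradients, singular-strategy location and ES/CS classification,
    pairwise invasibility plots, trade-off space maps), polymorphic
    evolutionary simulation on a trait lattice (branching, convergence,
    evolutionary suicide detection), and reproduction of lifespan and
    maturation-probability sweep experiments including frequency-dependent
    calibration and suicide-gap detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
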