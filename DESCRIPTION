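Package: tgkinetics
Title: Solid-State Decomposition Kinetics and Shelf Life from Thermogravimetric Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for solid-state thermal decomposition kinetics
    from thermogravimetric (TG) traces. Provides the classical integral kinetic
    model registry (nucleation, Avrami-Erofeev, geometric contraction, and
    diffusion models), conversion-degree computation from mass-loss curves,
    nonlinear Vyazovkin isoconversional estimation of the activation energy
    from multi-heating-rate nonisothermal runs (with the third-degree
    Senum-Yang approximation of the temperature integral), a fixed-hidden-weight
    multilayer-perceptron ensemble that combines ten kinetic models by
    pseudo-inverse least squares on isothermal runs, and Arrhenius
    extrapolation of fitted rate constants to t90 shelf-life estimates at
    storage temperatures. Includes synthetic TG data generators so the whole
    chain is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
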