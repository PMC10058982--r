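Package: aortaUQ
Title: Image-Based Arterial Stiffness Estimation and Hemodynamic
    Uncertainty Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the elastic modulus of an arterial wall from
    flow-area (QA) curves as extracted from phase-contrast MRI, using the
    pulse-wave-velocity based chi-method, and propagates the associated
    parametric uncertainty through a deterministic haemodynamic model by
    non-intrusive generalized Polynomial Chaos (gPC) with Gauss-Legendre
    quadrature and a Legendre basis. The deterministic model is a
    lumped-parameter (0D) network of compliant aortic segments with
    three-element Windkessel outlets, producing flow and area waveforms
    at named cross-sections. Includes a synthetic-data generator with
    known ground truth, time-resolved stochastic summaries (mean,
    standard deviation, probability densities), CSV/JSON interfaces and
    a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
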