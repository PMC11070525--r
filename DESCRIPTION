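Package: phikin
Title: Phi-Order Photokinetics under Polychromatic Light
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of unimolecular photoreaction kinetics
    driven by polychromatic light.  Integrates the wavelength-summed
    photokinetic rate law with a fixed-step fourth-order Runge-Kutta scheme
    for arbitrary photostep mechanisms, fits the resulting concentration and
    absorbance traces with the Phi-order model equation by multistart
    Levenberg-Marquardt least squares, and provides the derived procedures:
    initial-rate metrics, spectator-molecule and initial-concentration
    studies, wavelength-range-of-optimal-reactivity determination,
    actinometer standardization, and quantum/photonic yield estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
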