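Package: sho
Title: Closed-Form Analysis and Design of a Two-Species Harmonic
    Oscillator Reaction Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a six-reaction, two-species mass-action network whose
    dynamics are linear and whose Jacobian has pure imaginary eigenvalues, so
    that both species' concentrations are exact sinusoids. Provides the
    closed-form time-domain solution and its oscillation characteristics
    (frequency, amplitude, phase, DC offset), an independent ODE-integration
    oracle with SBML and Antimony export, a multi-start bounded least-squares
    algorithm that finds kinetic constants and initial concentrations
    achieving desired oscillation characteristics, analytic and numerical
    relative sensitivities of the frequency, and a Monte-Carlo feasibility
    study of the design under truncated-normal kinetic-constant variability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
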