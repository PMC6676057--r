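Package: istco
Title: Inspired Sinewave Technique Cardiac Output: Simulation, Estimation
    and Method-Comparison Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation of a single-compartment tidally ventilated
    lung exchanging a soluble tracer gas (nitrous oxide) with pulmonary
    capillary blood under sinusoidal inspired forcing; recovery of pulmonary
    blood flow and effective lung volume from the damped, phase-shifted
    expired sinewave over rolling windows (the inspired sinewave technique);
    a virtual porcine study generator emulating pharmacological cardiac
    output manipulation with intermittent triplicate thermodilution
    reference measurements; and the method-comparison toolkit used to
    validate continuous cardiac output monitors: interchangeability rate,
    repeated-measures Bland-Altman limits of agreement, four-quadrant
    concordance, half-circle polar plot analysis, and the trend
    interchangeability method (TIM).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
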