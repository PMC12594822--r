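Package: iontotwin
Title: Digital Twin of a Wireless Bioelectronic Wound Actuator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation of a wireless, closed-loop iontophoretic
    wound actuator: quantized current-DAC actuation and ADC sensing with
    two-point linear calibration, a seeded synthetic wound-load model with
    compliance-limited current delivery, pulsed closed-loop current control
    with electric-field and fluoxetine treatment scheduling, Faradaic
    (coulometric) dose accounting, SD-card-style telemetry logging with
    power-loss resume, and energy-budget estimation. Every control and
    dosing behaviour of the device can be simulated, logged and verified
    without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
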