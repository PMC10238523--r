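Package: coroflow
Title: Patient-Specific Lumped-Parameter Simulation of Coronary and Global
    Hemodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Closed-loop zero-dimensional (lumped-parameter) model of the left
    heart, systemic, pulmonary and three-branch coronary circulation built
    entirely from non-invasive measurements (Doppler echocardiography, CT
    coronary cross-sections and cuff pressures). Circuit elements are derived
    from the measurements (Murray-law resistance allocation, energy-loss valve
    coefficients, time-varying elastance chambers with an intramyocardial
    coronary pressure source), the stiff ODE system is integrated to a periodic
    limit cycle, free parameters are tuned to the measured brachial pressures
    and forward LVOT stroke volume, and global plus per-branch coronary
    hemodynamic metrics, pre/post-intervention deltas and a parameter
    sensitivity harness are reported as tidy tibbles.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
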