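Package: ventbench
Title: Desk-Scale Workbench for Ventilator Flow Control: PID Versus Fuzzy Logic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates an electropneumatic ventilator flow-control loop at the
    desk: a synthetic single-compartment test-lung and proportional-valve plant
    with hysteresis, actuator lag, sensor delay and noise, cough and leak
    disturbances; a discrete PID controller with Ziegler-Nichols tuning support;
    a Mamdani fuzzy-logic controller on flow error and error rate with a 5x5
    rule base; ARX system identification to fourth-order discrete transfer
    functions; Jury and Nyquist stability analysis with gain and phase margins;
    and the conformity and repeatability statistics used to compare controllers
    (Bland-Altman limits of agreement, Fisher-Snedecor variance test,
    finite-population sample size). All experiments run on the built-in
    synthetic plant, so the PID-versus-fuzzy comparison is reproducible without
    hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
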