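Package: rivarif
Title: Rivaroxaban-Rifampin Drug Interaction Simulation with Time-Dependent
    CYP3A4 and P-gp Induction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the pharmacokinetic interaction between rivaroxaban
    (victim) and rifampin (perpetrator) with a coupled ordinary differential
    equation model: an enzyme-turnover induction model for hepatic CYP3A4 and
    renal P-glycoprotein, a one-compartment rifampin model with metabolic
    self-induction, and a pathway-partitioned rivaroxaban disposition model.
    Provides fixed-step fourth-order Runge-Kutta integration with oral dosing
    events, per-day Cmax and AUC exposure metrics against a reference
    exposure window, fold-error model validation, dosing-regimen searches for
    co-medication, initiation and rifampin-withdrawal scenarios, and a
    synthetic patient/observation generator for self-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
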