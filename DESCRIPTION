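Package: neovanc
Title: External Validation of Neonatal Vancomycin Population
    Pharmacokinetic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating the a-priori predictive performance of
    neonatal vancomycin population pharmacokinetic (popPK) models against
    therapeutic drug monitoring data.  Provides a declarative covariate-model
    registry with the Chung 2023 neonatal model built in, a closed-form
    one-compartment intermittent-infusion prediction engine (Sawchuk-Zaske
    superposition), prediction-error metrics (ME, RMSE, relative mean and
    median error, p30) with nonparametric bootstrap confidence intervals and
    predefined acceptance criteria, visual predictive checks on the cohort's
    actual dosing and sampling design, trough-stratified clinical-outcome
    tables with modified neonatal RIFLE acute kidney injury classification,
    and a synthetic cohort generator with known ground truth so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
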