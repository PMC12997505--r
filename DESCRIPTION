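Package: becdose
Title: Model-Informed Dose Selection from Blood Eosinophil Pharmacology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for model-informed dose selection of long-acting anti-IL-5
    biologics from blood eosinophil count (BEC) pharmacology. Implements a
    Bayesian nonlinear mixed-effects dose-time response model for log BEC with
    a time-varying ED50, quantitative decision-making (go/consider/no-go)
    probability grids against reference pharmacology thresholds, simulation of
    Phase IIb dose-ranging trials with negative-binomial exacerbation
    endpoints (class-effect GLM and nonlinear Emax fits, ED90 precision), and
    a population PK/PD indirect-response (turnover) model of eosinophil
    suppression for cross-indication dose selection. A synthetic-data
    generator with known ground truth replaces proprietary clinical inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    coda,
    deSolve,
    jsonlite,
    rjags,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
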