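Package: refluxscint
Title: Scintigraphic Gastro-Oesophageal Reflux Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates dynamic and delayed gamma-camera reflux studies for
    configurable patient cohorts using a six-compartment tracer-kinetics model
    with Poisson counting noise, extracts and grades region-of-interest
    time-activity curves (declining / flat / rising), detects pulmonary
    aspiration of refluxate on delayed images by a line-profile threshold
    relative to background, and benchmarks the scintigraphic markers against
    simulated pH-monitoring and manometry covariates with Fisher's exact test,
    predictive values, Pearson correlation and ROC analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
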