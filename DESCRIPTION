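Package: htngap
Title: Detecting Undiagnosed Hypertension from Claims and EHR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating the burden of undiagnosed hypertension in a
    health care delivery organization. Implements nested multi-source case
    definitions for hypertension (billing claims, EHR problem list, in-office
    blood-pressure criteria) and for three comorbidities (obesity, diabetes,
    chronic kidney disease); an expected-prevalence estimator that applies a
    stratum-specific reference prevalence table to a population's demographic
    and comorbidity composition (indirect standardization with standard-error
    propagation); and predicted-versus-observed gap reports with
    percentage-point differences, additional-patient counts and one-in-N
    ratios, overall and per organization. A synthetic patient-level
    cohort generator with known ground truth makes every stage testable
    without access to protected health information.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
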