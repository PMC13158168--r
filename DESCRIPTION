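Package: bnctdose
Title: Patient-Specific Whole-Body Out-of-Field Dosimetry for BNCT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrated measurement-simulation workflow for whole-body
    out-of-field dosimetry in accelerator-based boron neutron capture therapy
    (BNCT). Converts multifoil (Au, Mn, Al) activation measurements into
    reaction rates, unfolds per-energy-region normalization factors against a
    reference 3x3 response matrix, scales reference per-region dose components
    (boron, nitrogen, hydrogen) into biologically weighted dose, adds measured
    gamma dose, evaluates ambient dose equivalent H*(10), and reports
    EQD2-normalized out-of-field dose metrics for patient cohorts. Includes a
    parametric synthetic reference library and cohort generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
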