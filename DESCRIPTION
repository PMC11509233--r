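Package: pvsignal
Title: Disproportionality-Based Safety Signal Detection for Spontaneous
    Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection in spontaneous
    reporting system (SRS) data such as KAERS, FAERS or VigiBase extracts.
    Reads report-level adverse drug event tables, applies the standard
    cleaning cascade (masked-code removal, missing-value exclusion, study
    window restriction, case-series deduplication, minimum-case inclusion),
    builds 2x2 contingency tables for every drug-event pair, and computes
    the proportional reporting ratio (PRR), reporting odds ratio (ROR) with
    Woolf 95% confidence intervals, Pearson chi-squared statistic, and the
    Bayesian confidence propagation neural network information component
    (IC) with its 95% lower credible bound.  A tri-criteria rule combining
    all three indices flags definitive signals.  Includes a seeded synthetic
    SRS generator with embedded ground-truth signal pairs for validation and
    calibration studies, demographic summarisation, per-drug signal tables
    with label-expectedness annotation, positive-control validation, and
    heatmap matrix export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
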