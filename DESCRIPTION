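Package: nestsub
Title: Multiplicity-Adjusted Tests for Nested Biomarker-Defined Subpopulations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Confirmatory testing of treatment effects in nested (and general)
    subpopulations defined by thresholding a continuous biomarker. Implements
    Sidak-adjusted t-tests, group-sequential Pocock and O'Brien-Fleming type
    critical boundaries with quantile substitution to the t scale,
    variance-adjusted plug-in covariance matrices that remain valid under
    unadjusted prognostic biomarker effects, sequential regression tests,
    weighted inverse normal combination tests, multiplicity-adjusted p-values,
    general (non-nested) subgroup tests including STEPP tail-oriented sets,
    and a Monte-Carlo engine for family-wise error rate, disjunctive power and
    sample-size computations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, mvtnorm, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
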