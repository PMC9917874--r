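Package: silacturnover
Title: Protein Turnover Analysis for Dynamic-SILAC Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates protein degradation rate constants and half-lives from
    pulsed (dynamic) SILAC heavy/light peptide ratio tables. Aggregates
    peptide ratios to protein level by the median, calibrates a
    heteroscedastic technical-variability model SD(r) = sqrt(alpha^2 +
    beta^2 r^2) from peptide replicate spread, fits first-order label
    incorporation kinetics ln(r + 1) = k t by weighted least squares,
    computes intensity-based relative protein abundance under a steady-state
    assumption, and performs two-group cohort comparisons of half-life and
    abundance with interval binning, quadrant classification, and a
    complex-versus-random half-life coherence analysis. Includes a
    synthetic-cohort generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    minpack.lm,
    stats,
    utils,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
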