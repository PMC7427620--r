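Package: qeegnorm
Title: Quantitative EEG Analysis with Age-Regression Normative Statistical Parametric Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative EEG (qEEG) analysis at scalp and source level:
    epoch-averaged cross-spectral matrices on a fine narrow-band frequency
    grid, coherence and phase topography, the classical broad-band model
    (absolute power, relative power, mean frequency per band), Global Scale
    Factor correction of recording gain, a spherical-head analytic lead field
    with a ridge-regularized frequency-domain distributed inverse solution
    for source power spectra, age-regression normative models (mean and
    standard deviation of log spectra as polynomials in log age), z-score
    statistical parametric maps against those norms, and family-wise-error
    control of the z-maps by the maximum-statistic criterion. Includes a
    seeded synthetic-data module (normative cohorts with age-dependent
    spectra and single-dipole scalp simulations) and a plain-text epoch
    interchange format.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    tibble,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
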