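Package: vasoreact
Title: Vasomotor Response Analysis for Respiratory Muscle Training Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studies of vasomotor response to
    respiratory muscle training (RMT). Computes flow-mediated dilation
    (%FMD) with shear-rate normalization from brachial-artery diameter and
    velocity time series, frequency-domain heart-rate variability (LF/HF
    band powers, normalized units) from RR-interval tachograms,
    inter-session reliability statistics (two-way mixed ICC, SEM%, MDC95%),
    isocapnic-hyperpnoea training prescriptions, and the group-comparison
    statistics of a two-group pre/post design (paired and unpaired t-tests,
    mixed-design two-way ANOVA with Holm-Sidak post hocs). Includes a
    synthetic-cohort generator that emulates hyperaemic diameter/velocity
    kinetics, RR series with tunable spectral band power, and programmed
    training effects, so the full pipeline is testable without trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
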