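Package: wbiscreen
Title: Validation Analytics for the Well-Being Index Screening Instrument
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to validate composite well-being screening instruments such as
    the 9-item Well-Being Index (WBI) against distress and professional-consequence
    reference standards. Computes the WBI composite score, derives half-standard-
    deviation quality-of-life and fatigue outcome definitions, and stratifies
    respondents by exact score: per-stratum odds ratios (Woolf intervals),
    stratum-specific likelihood ratios (Katz intervals), Bayes posttest
    probabilities, sensitivity/specificity, empirical ROC curves with tied ordinal
    scores, and likelihood-ratio-based threshold selection. Includes
    first-principles two-group and contingency tests, a latent-trait synthetic
    cohort generator for end-to-end testing without survey data, and table/figure
    reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
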