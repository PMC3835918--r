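Package: warmclock
Title: Warm-Ischemia Time-Course Analysis of Bead-Array Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the effect of delay to cryopreservation (warm ischemia)
    on genome-wide expression measured with Illumina-style bead arrays.
    Provides a synthetic-data generator emulating a paired central/peripheral,
    two-tumor-type, four-timepoint harvest design with known ground truth;
    detection-p-value and P95/P05 quality control; log transformation,
    quantile normalization and probe filtering; an inverse-variance weighted
    overall expression-decay estimate (percent per hour) from a
    random-intercept mixed model; per-probe quadratic time-course F-tests with
    false-discovery-rate control; Neyman smooth rank contrasts for
    pre-specified gene sets; literature direction-consistency analysis via
    block-logistic regression; and hierarchical clustering with fold-change
    summaries and a tabular run report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    lme4,
    lmerTest,
    matrixStats,
    sandwich,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
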