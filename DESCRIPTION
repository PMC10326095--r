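Package: volagree
Title: Agreement Analysis for CAD-Based Pulmonary Nodule Volumetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for method-comparison studies of computer-aided diagnosis
    (CAD) systems that measure pulmonary nodule volumes. Provides a seeded
    synthetic phantom-study generator (randomized nodule arrangements,
    per-system detection and relative-error models, including a bimodal
    systematic error for large solid nodules), the volumetric agreement
    statistics used in such studies (relative volumetric error, absolute and
    relative volume differences, Bland-Altman limits of agreement, paired
    nonparametric tests), and a Lung-RADS classification-impact analysis
    (category assignment from measured volumes, cross-tabulation between
    systems, concordance and correctness summaries), together with a
    configuration-driven end-to-end pipeline and CSV/JSON reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
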