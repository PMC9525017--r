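Package: csvdbag
Title: Regional Brain-Age Gap Analysis for Cerebral Small Vessel Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trains global and regional brain-age prediction models
    (radial-basis-function support vector regression with nested
    cross-validation) on grey-matter-volume features from a healthy cohort,
    estimates brain-age gaps (BAG) in an application cohort, classifies
    cerebral small vessel disease (CSVD) from MRI markers by a median-split
    rule, compares BAG between groups with covariate-adjusted ANCOVA and
    partial eta-squared effect sizes under Bonferroni control, and tests
    whether regional BAG mediates CSVD-related cognitive impairment using
    bias-corrected and accelerated (BCa) bootstrap mediation. Includes a
    synthetic cohort simulator with known ground truth for end-to-end
    validation and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
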