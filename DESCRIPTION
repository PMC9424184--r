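Package: ckdburden
Title: Comparative Risk Assessment of Modifiable Risk Factors for Chronic Kidney Disease Burden
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Attributes chronic kidney disease (CKD) case burden to modifiable
    risk factors with the comparative risk assessment framework: population
    attributable fractions (PAFs) against theoretical-minimum-risk exposure
    distributions (TMREDs), census-standardized exposure trajectories from an
    open longitudinal cohort, Monte-Carlo uncertainty propagation for relative
    risks and disease prevalence, and two-stage random-effects projection of
    exposures and attributable cases twenty years forward. Includes a
    calibrated synthetic-cohort generator emulating a Chinese national
    nutrition-survey panel so the full pipeline runs without restricted data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    sandwich,
    lmtest
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
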