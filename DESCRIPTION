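Package: nwascreen
Title: Nutrient-Wide Association Screening for Survival Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for nutrient-wide association studies (NWAS): agnostic
    screening of many correlated dietary exposures against a time-to-event
    outcome with stratified Cox proportional hazards models on the age time
    scale, multiplicity correction by a permutation-constructed null
    distribution false discovery rate (with Benjamini-Hochberg as a
    sensitivity analysis), replication of selected signals in a case-cohort
    design via Prentice-weighted Cox regression with robust variance, and
    pooling of cohort-specific estimates by DerSimonian-Laird random-effects
    meta-analysis. Includes a synthetic cohort generator emulating the data
    structure such studies assume (correlated food and nutrient intakes,
    energy confounding, multi-centre stratification, delayed entry, disease
    subtype labels and a case-cohort subsample), preprocessing utilities
    (exclusion cascades with audit trails, residual-method energy adjustment,
    standardization, quartile coding, extreme energy-ratio trimming), and
    reporting tables for volcano and forest plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
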