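Package: ocaa
Title: Omics Ageing Clocks, Variance Overlap and Age-Acceleration
    Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds chronological-age prediction clocks from multiple omics
    feature matrices by penalised regression, quantifies how clocks overlap
    in the variance of chronological age they explain (part-correlation
    variance partitioning and a scaled excess-overlap statistic against an
    independent-sampling null), and estimates the effect of omics clock age
    acceleration (OCAA) on risk factors and incident disease in units of
    years of chronological age.  Ships a synthetic-cohort generator that
    reproduces the statistical structure the analysis assumes (multiple
    assays with tunable informativeness, a latent age-acceleration
    component, risk factors, and proportional-hazards disease incidence
    with censoring and prevalent cases), so the whole pipeline is testable
    without access-controlled cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    survival,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
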