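Package: sdohci
Title: Multidimensional Deprivation Indices for Social Determinants of Health Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds Alkire-Foster dual-cutoff multidimensional deprivation
    indices over structural and social determinants of health (S/SDOH)
    indicators collected in aging cohorts. Provides a declarative indicator
    registry (37 indicators nested in 10 factors across 3 dimensions of the
    NIA Health Disparities Research Framework), standard-deviation and
    composite deprivation rules including a polychoric principal-component
    asset index, cognitive-status classification (MoCA cutoff and PACC
    z-score composite), the adjusted headcount ratio M0 with indicator and
    factor contribution decompositions, subgroup decomposition with bootstrap
    inference, logistic models of cognitive impairment on deprivation burden
    with Tjur R-squared, descriptive table builders, and a seeded synthetic
    cohort generator for end-to-end testing without access to restricted
    cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
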