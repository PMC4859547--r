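Package: csehealth
Title: Child Social Exclusion Index Construction and Small-Area Child Health
    Outcome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a small-area composite index of children's risk of social
    exclusion from census-style indicators (domain scores by principal
    components, an exponential rank transformation, and child-population
    weighted quintiles), computes age-standardised rates of potentially
    preventable hospitalisations and quintile-level avoidable-mortality rates,
    and quantifies the index-outcome association through weighted correlations,
    quintile concordance cross-tabulations, gradient tests, polynomial
    regression residuals analysed by remoteness, and contingency chi-square
    tests. Includes a synthetic small-area data generator with a latent
    disadvantage factor so the full pipeline is testable without restricted
    unit-record data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
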