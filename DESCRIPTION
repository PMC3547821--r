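Package: evohet
Title: Evolving Heterogeneity in Aging: Gompertz Mortality, Trait Evolution
    and Population Mortality Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates populations of individuals whose heritable
    resource-allocation trait controls a Gompertz mortality hazard, either
    through the aging rate (HRM) or the aging timing (HTM), and a
    trait-proportional probability of reproduction.  Populations evolve over
    non-overlapping generations, by weight-proportional competition for
    reproduction with mutation, towards quasi-stationary trait
    distributions.  Provides continuous-time (Gillespie) and discrete-time
    stochastic engines, an infinite-population deterministic
    distribution-operator engine, demographic estimators (age-specific
    mortality with person-time exposure, empirical survival, mortality-shape
    classification, lifespan modality via a dip statistic), and drivers for
    environment scans, mutation-rate scans, oldest-old analysis,
    stress-induction predictions, heat-shock survival and subpopulation
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
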