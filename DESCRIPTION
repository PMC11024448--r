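Package: netmmm
Title: Multiple-Membership and Proximal Network Exposure Models for
    Sociometric Injection-Network Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing engagement in HIV prevention services
    (HIV testing, medication for opioid use disorder, syringe services)
    as a function of injection-network exposures in sociometric cohorts
    of people who inject drugs. Assembles a deduplicated reciprocal
    network from coupon-referral records, enumerates direct and socially
    proximal (path length <= 3) ego-networks, constructs any/proportion
    network-exposure covariates, and fits three model families: Bayesian
    multilevel multiple-membership logistic models in which each ego
    belongs fractionally to its injecting partners' random effects,
    cross-classified dyad-level logistic models with crossed ego and
    alter intercepts and partnership-characteristic effect modification,
    and egocentric logistic models with a-priori adjustment plus p < 0.10
    covariate screening. A synthetic-cohort generator reproduces the
    coupon-referral recruitment process with duplicate-recruitment
    cross-links and a mechanistic outcome process with known
    coefficients for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
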