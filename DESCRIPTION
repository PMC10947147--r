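Package: painscape
Title: Small-Area Estimation of Chronic Pain Prevalence by Multilevel
    Regression and Poststratification
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Estimates neighbourhood-level (LSOA) prevalence of chronic
    and high-impact chronic pain from survey data using multilevel
    regression and poststratification (MRP).  Provides a synthetic-data
    generator emulating a three-local-authority English study region with
    known ground truth, a Bayesian two-level logistic regression fitted by
    Polya-Gamma augmented Gibbs sampling (with a fast penalised-likelihood
    alternative via 'lme4'), poststratification over LSOA age-sex
    population cells, multiplicative ethnicity correction factors,
    stratified bootstrap percentile confidence intervals, and
    neighbourhood inequality summaries (prevalence quintiles and the 20:20
    metric).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    coda,
    digest,
    lme4,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
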