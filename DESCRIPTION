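Package: ordtree
Title: Hierarchical Latent-Trait MPT Modeling with Ordinal-Constraint Bayes Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for Bayesian hierarchical multinomial processing tree (MPT)
    modeling with theory-informed priors. Provides EQN model import/export and
    built-in two-high-threshold source-monitoring (2HTSM) model constructors, a
    probit-link latent-trait hierarchy with multivariate-normal individual
    differences, named prior presets, prior- and posterior-predictive checking
    (including T1/T2 posterior-predictive p values), and Bayes factor tests of
    equality and (dis)ordinal constraints across experimental conditions via
    Savage-Dickey density ratios and the unconditional encompassing counting
    method, with transitivity composition, stability repetition, sensitivity
    grids, and individual-level ("every participant") tests. Includes a
    synthetic-data generator for source-monitoring study designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    coda,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
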