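Package: ordlvm
Title: Latent-Variable Association Tests for Ordinal Traits and Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests association between an ordinal phenotype and an ordinal
    genotype while adjusting for continuous covariates, by modelling both as
    discretized coordinates of a latent multivariate normal vector with
    unit-diagonal covariance. The conditional latent correlation between
    genotype and phenotype given the covariates is estimated by solving a
    pairwise-likelihood generalized estimating equation; its sandwich
    (M-estimation) variance and the delta method yield an asymptotically
    standard-normal Wald statistic. Includes ordered probit and
    proportional-odds logit comparators, seeded generators for the latent
    normal discretization and proportional-odds simulation mechanisms, and a
    scenario-grid runner that aggregates Monte-Carlo rejection rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mvtnorm,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
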