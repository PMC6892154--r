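Package: newsyipen
Title: Scoring, Measurement Models and Validity Analyses for the NEWS-Y-IPEN
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements the measurement-and-validation pipeline for the
    Neighborhood Environment Walkability Scale for Youth, IPEN Adolescent
    version (NEWS-Y-IPEN): the subscale scoring protocol (including the
    weighted residential-density score and the Denmark and Nigeria variants),
    normal-theory maximum-likelihood confirmatory factor analysis on raw or
    pooled within-cluster covariance matrices with CFI, RMSEA (noncentral
    chi-square confidence interval) and SRMR fit indices, empty multilevel
    models partitioning subscale variance between countries, and
    construct-validity linear mixed models of subscale scores on binary
    area-level socio-economic status and walkability. A synthetic-cohort
    generator parameterized from the published country sample sizes, subscale
    distributions and standardized factor loadings provides multi-country
    clustered data with the structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
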