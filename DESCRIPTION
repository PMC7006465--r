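Package: matbias
Title: Comparative Analysis of Sex-Biased Maturation on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for comparative analyses of sex differences in age at
    sexual maturation. Builds derived sex-bias variables (maturation bias,
    sexual size dimorphism, polygamy bias, transformed adult sex ratio) from
    per-sex trait measurements, fits phylogenetic generalized least squares
    (PGLS) regressions with maximum-likelihood estimates of Pagel's lambda
    across samples of candidate phylogenies, and performs confirmatory
    phylogenetic path analysis by d-separation (Fisher's C, CICc model
    ranking, standardized path coefficients), including a nondirectional
    variant based on lambda-rescaled independent contrasts. A synthetic-data
    module simulates trees and trait tables under a chosen causal model so
    every stage of the pipeline can be validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    nlme,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
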