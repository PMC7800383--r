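Package: hemicoal
Title: Hemiplasy and Homoplasy Probabilities under the Multispecies Network Coalescent
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic probabilities of hemiplasy and homoplasy for a binary
    trait on a rooted three-taxon phylogenetic network with an instantaneous
    introgression pulse, together with a simulation-based inference pipeline
    for larger trees and networks: a structured-coalescent gene-tree simulator
    with introgression pulses, a Poisson binary-trait overlay, focal-locus
    filtering against an observed trait pattern, Fitch-parsimony baselines,
    and a concordance-factor regression for converting substitutions-per-site
    branch lengths into coalescent units.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
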