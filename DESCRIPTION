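Package: pollendrive
Title: Dynamics of Pollen-Killer Segregation Distorters in Selfing Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic two-locus toxin-antidote model of pollen-killer
    segregation distorters in hermaphroditic plants with selfing,
    recombination and pollen redundancy. Provides the one-generation
    genotype-frequency recursion and long-run iteration to equilibrium,
    parameter sweeps over recombination and selfing rates, minimum invasion
    frequencies and invasion thresholds, Patterson's f4 statistic with a
    quadruplet-maximum introgression indicator, empirical percentile
    p-values and Fisher's combined probability test, plus seeded synthetic
    generators: a finite-population Wright-Fisher counterpart of the mating
    model and multi-species biallelic allele-frequency data evolved on a
    species tree with an optional introgression event.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
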