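Package: pacifex
Title: Population Genomics of Serial Founder Range Expansions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for reconstructing island range expansions from reduced
    representation genotype data. Builds polarized one- and two-population
    site frequency spectra with hypergeometric projection, computes diversity
    and differentiation statistics (pi, observed heterozygosity, Tajima's D,
    Weir-Cockerham F_ST with permutation tests, the directionality index psi,
    Evanno's delta-K), tests isolation by distance with Mantel permutations,
    builds neighbour-joining trees from identity-by-state distances, and fits
    two-population founder-event demographic models to the joint spectrum by
    Poisson composite likelihood over a Monte-Carlo structured-coalescent
    engine with an AIC-weighted sequential restart optimizer. A built-in
    multi-deme coalescent simulator generates complete synthetic data sets
    (genotypes, outgroup states, coordinates) with serial founder structure.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    ggplot2,
    generics,
    vcfR,
    ape,
    geosphere,
    yaml,
    jsonlite,
    stats,
    utils,
    withr,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
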