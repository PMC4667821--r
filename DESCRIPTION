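Package: phyloskew
Title: Phylogenetic Skew, Diversity Indices, and Priority Mapping for
    Community Phylogenetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for community phylogenetics on geo-referenced species
    occurrences and a time-scaled phylogeny. Implements the generalized
    birth-death likelihood of ordered divergence times, a two-step
    maximum-likelihood procedure estimating speciation and extinction
    rates for a meta-community and an effective sampling proportion for
    each local community, and the derived phylogenetic skew (PS) and
    phylogenetic-clade evenness (PE) indices. Also computes species
    richness, Faith's phylogenetic diversity and average taxonomic
    distinctness per 1x1 degree grid cell, ranks cells by percentile,
    selects top-percentile priority conservation cells, and ships a
    synthetic-data generator (birth-death trees with known rates plus
    occurrence grids with planted latitudinal clade skew) so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    ape,
    lhs,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
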