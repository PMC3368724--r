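Package: synmapr
Title: Synthetic Linkage Map Construction and Comparative Synteny Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds a synthetic (consensus) genetic linkage map from
    heterogeneous doubled-haploid segregation datasets. Distance-only
    published maps are converted into pseudo-gamete vectors via the inverse
    Kosambi map function so that they can be merged with raw genotype data;
    cross-dataset conflicts in linkage-group assignment and marker order are
    screened and resolved with auditable rules; markers are ordered per
    linkage group by simulated annealing, taboo search, windowed
    permutations, or an exact subset dynamic program, using the two-point
    recombination fraction as the mapping function. Downstream comparative
    tools detect whole-genome-duplication homeologs through arm-level Oxford
    grids with an exact binomial enrichment test, filter BLAST tabular
    homology results with best-hit/HSP/uniqueness rules, prune cross-species
    Oxford grids (orphan removal, metacentric reassignment, homeolog
    parsimony), project chromosome arms onto reconstructed ancestral
    proto-chromosomes, and export MapChart-compatible alignments. A
    ground-truth simulator of doubled-haploid segregation and homology
    tables supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
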