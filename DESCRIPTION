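Package: hgtscan
Title: Detection of Horizontal Gene Transfer in Plant Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for detecting foreign (horizontally
    transferred) DNA in plant mitochondrial genomes. Mitogenomes are clipped
    into non-overlapping windows and classified against a taxonomically
    labeled reference panel by seed-and-extend local similarity search;
    contiguous foreign windows are merged into segments with homology-refined
    boundaries. Donor lineages of foreign genes are inferred by progressive
    alignment, Jukes-Cantor distances, neighbor joining, and nonparametric
    bootstrap sister-clade calls. C-to-U RNA editing sites are called from
    pileup evidence and used to discriminate DNA-mediated transfer from
    retroprocessing; relative expression (TPM) of foreign versus native genes
    is compared with a Mann-Whitney U test; foreign sequence shared across
    species is quantified via maximal-exact-match anchoring. A synthetic-data
    module generates chimeric mitogenomes with known ground truth so that
    every stage is testable end to end without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    ape,
    Biostrings,
    data.table,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
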