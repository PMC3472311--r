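Package: panoen
Title: Pan-Genome Comparison of Oenococcus oeni Strain Collections
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style toolkit for comparative pan-genome analysis of
    small bacterial strain collections, modelled on the wine bacterium
    Oenococcus oeni. Builds ortholog loci from reciprocal-best-hit protein
    homology refined by genomic synteny, derives tri-state
    (intact/pseudogene/absent) presence-absence matrices, computes core and
    pan genome rarefaction over all strain combinations, screens genomes for
    horizontally transferred segments by sliding-window amino-acid identity
    against donor proteomes, detects and classifies prophage elements at tRNA
    attachment sites via direct-repeat (att) scanning, genotypes variable
    gene cassettes such as exopolysaccharide loci, calls pathway and
    transporter-complex completeness, and infers neighbor-joining core-gene
    phylogenies with bootstrap support. Ships a forward simulator of strain
    collections with exhaustive ground truth for benchmarking every stage,
    and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    igraph,
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    stringr,
    rlang,
    vctrs,
    ggplot2,
    data.table,
    generics,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
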