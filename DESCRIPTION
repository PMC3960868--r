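Package: famscan
Title: Profile-HMM Gene-Family Annotation and Duplication Analysis for
    Plant Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A semi-automatic gene-family discovery toolkit modelled on
    MADS-box gene annotation workflows. Builds a profile hidden Markov
    model from a seed alignment of domain exemplars, searches predicted
    proteomes and six-frame-translated genome assemblies for domain
    hits, extracts candidate loci in a fixed window around each detected
    domain, calls and merges gene models from the CDS and genome tracks,
    classifies genes into types and groups by their position in a
    reference-anchored neighbor-joining phylogeny, and summarises
    duplication dynamics (species-specific clades, lineage-specific
    duplication counts, tandem/proximal/distal duplicate classes). A
    seeded synthetic-data generator produces genomes, proteomes, seed
    alignments and truth manifests so the whole pipeline is testable
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    ape,
    phangorn,
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    generics,
    ggplot2,
    yaml,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
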