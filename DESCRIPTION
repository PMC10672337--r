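Package: endosym
Title: Comparative Genomics of Reduced Endosymbiont Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics toolkit for panels of small, AT-rich obligate
    endosymbiont genomes (such as whitefly 'Candidatus' Portiera lineages).
    Reads annotated genomes from GenBank flat files or FASTA, computes genome
    summary statistics, detects single-copy orthologs by reciprocal best hits
    on global protein alignments, estimates synonymous and nonsynonymous
    substitution rates with the Nei-Gojobori (1986) method, computes codon
    usage bias statistics (positional GC, PR2 coordinates, GC3s, Wright's
    effective number of codons) with group-level PR2, neutrality-plot and
    ENC-plot analyses, measures genome relatedness by ortholog-based ANI/AAI
    and MinHash (Mash) distances, builds neighbor-joining trees, and
    classifies genomes into genetic groups under ANI/AAI thresholds. Includes
    a codon-level substitution simulator that generates fully annotated
    synthetic genome panels with controlled codon bias, divergence structure
    and selection strength, so every stage of the pipeline is testable
    without downloading data.
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
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    Biostrings,
    IRanges,
    ape,
    igraph,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    seqinr,
    optparse
Config/testthat/edition: 3
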