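Package: rqscreen
Title: Screening Animal Genomes for Rhodoquinone-Based Anaerobic
    Mitochondria Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies molecular signatures of rhodoquinone (RQ) based
    facultative anaerobic mitochondria in animal proteomes and genome
    assemblies. Implements a four-marker diagnostic-residue panel (COQ-2,
    MEV-1, TDO-2, ETFDH), affine-gap pairwise alignment (global and local)
    with six-frame translation for nucleotide inputs, per-species residue
    calling and classification, Fitch-parsimony ancestral-state
    reconstruction on a species tree, and redox-balanced ATP-yield
    accounting for anaerobic fermentation pathways (homolactate, opine,
    malate dismutation). A synthetic-data generator plants known genotypes
    in decoy-laden proteomes and nucleotide contigs so the whole pipeline
    can be validated end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
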