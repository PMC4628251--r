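Package: sef
Title: Identification of Syntenic Enhancers with Divergent Sequences
Version: 0.1.0
Authors@R:
    person("Morgan", "Reyes", email = "mreyes@example.org", role = c("aut", "cre"))
Description: A pipeline for identifying candidate enhancers that are
    sequence-conserved within groups of closely related vertebrate species
    but divergent between distant groups, yet lie in orthologous introns and
    are therefore likely derived from a common ancestral regulatory element.
    Implements orthologous-intron derivation from bracketing exon matches,
    conserved-element calling with a two-state phylogenetic hidden Markov
    model, cross-group subtraction by alignment overlap and seed-and-extend
    homology search, epigenetic (H3K4me1/H3K4me3) and Gene Ontology
    prioritization, three-way shared-motif discovery with Karlin-Altschul
    chance statistics, position-frequency-matrix annotation of shared
    motifs, and positivity scoring of zebrafish reporter-assay expression
    tables with cross-species consistency calls.  Ships a synthetic-data
    generator that plants conserved elements, shared motifs, histone-mark
    peaks and assay counts with a full truth table, so that every stage is
    testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
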