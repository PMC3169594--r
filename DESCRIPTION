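Package: tm1annot
Title: Discovery and Annotation of Tm1 Foldback/Mutator-Family Transposons
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An annotation pipeline for Tm1, a family of class II DNA
    transposons of root-knot nematodes defined by composite, internally
    repetitive terminal inverted repeats (TIRs) and 8-10 bp target site
    duplications. Implements a seeded local-alignment search with X-drop
    extension and Karlin-Altschul statistics, a free-end-gap global
    aligner, opposite-orientation hit pairing into candidate elements, TIR
    delineation by terminal self-comparison, annotation of the A1/A2/B/C/D
    composite-TIR motif grammar, target-site-duplication and empty-site
    analysis with in-silico PCR, element classification
    (autonomous/deletion-derivative/histone-hairpin/MITE-like), and
    family-level summaries including sequence logos, Motif C length
    histograms and a bootstrapped neighbor-joining tree of MITE-like
    elements. A synthetic-genome generator with full ground truth supports
    end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
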