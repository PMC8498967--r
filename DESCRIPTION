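Package: TElandscape
Title: Transposable Element Landscape Characterization from Low-Coverage Genome Skims
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to characterize the transposable element (TE) community of a
    genome from low-coverage shotgun data and a classified repeat library:
    parsing of RepeatMasker-style hit tables and Wicker-style classification
    labels, per-base overlap-resolved genome-fraction tables, community ecology
    diversity indices (Shannon, Gini-Simpson) with cross-genome comparison,
    per-superfamily divergence landscapes with a deterministic amplification
    history / activity classifier, terminal-to-internal (TT:I) read-depth ratio
    estimation of ectopic recombination-mediated deletion, transcriptome TE
    annotation and expression summaries, greedy 80 percent-identity family
    clustering, and a fully seeded synthetic TE-genome generator providing
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Genetics, SequenceMatching, Transcriptomics, Annotation
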