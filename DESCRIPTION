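Package: famevol
Title: Comparative Genomic Analysis of Eutherian Gene Families
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable implementation of a eutherian comparative genomic
    analysis protocol for multi-member gene families such as the connexins:
    read-coverage based reliability classification of candidate coding
    sequences, codon-aware back-translation of protein alignments, pairwise
    nucleotide identity matrices with summary statistics and homologue
    banding, sliding-window conserved-region detection, duplication-timing
    and gene-expansion analysis, distance-based (neighbor-joining) trees
    with codon-column bootstrap, and a protein molecular-evolution test
    built on relative synonymous codon usage with motif, sequon and
    membrane-region annotation. Includes a seeded gene-family simulator
    that reproduces the statistical structure the analyses assume.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    phangorn,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Phylogenetics, SequenceMatching, Genetics, Alignment
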