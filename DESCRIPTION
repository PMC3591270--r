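Package: xenoexpress
Title: Reference-Free Comparative RNA-Seq Against an Annotated Anchor Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for comparative RNA-seq analysis of a species without a
    sequenced genome. Contigs from a de novo transcriptome assembly are assigned
    to the gene set of a well-annotated anchor species by best BLAST hit,
    contig-level expected read counts are aggregated to anchor-gene counts and
    normalized to transcripts per million with effective-length sums, and
    differential expression over an unreplicated time course is called with a
    negative-binomial exact test using a consecutive-pair median common
    dispersion. Downstream analyses are provided: assembly-completeness
    estimation from aligned/unaligned high-quality read homology-hit rates,
    gene-set enrichment over time (Fisher's exact test with an EASE variant),
    hierarchical clustering with multiscale-bootstrap edge support (BP/AU),
    longest-ORF coding analysis with a shuffled null, and qPCR concordance.
    A seeded synthetic-data generator emulates every input so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
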