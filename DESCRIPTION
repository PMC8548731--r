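Package: lncm6a
Title: Integrative Analysis of m6A Methylation on Long Non-Coding RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end workflow for studying N6-methyladenosine (m6A)
    methylation of long non-coding RNAs across two cellular states, as in
    MeRIP-seq studies of myoblast differentiation (growth-medium myoblasts,
    GM, versus day-4 myotubes, D4). Provides windowed IP-versus-input peak
    detection with a conditional binomial test, Fisher-exact differential
    methylation, RPKM normalization and a moderated negative-binomial Wald
    test for differential expression, peak placement over lncRNA exon
    architecture and transcript-scaled metagene profiles, DRACH/k-mer motif
    enrichment, four-quadrant methylation-by-expression integration with
    Pearson and Kolmogorov-Smirnov statistics, cis neighbor-gene pairing with
    hypergeometric over-representation analysis, and a fully synthetic data
    generator (genome, annotation, counts, truth tables) so every stage is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    methods,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    fgsea,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    GenomicRanges
Config/testthat/edition: 3
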