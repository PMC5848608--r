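Package: utrshift
Title: Alternative Polyadenylation Analysis from 3'-End Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies tandem 3' UTR usage from 3'-end sequencing (PA-seq
    style) tag data. Calls poly(A)-site clusters with internal-priming
    filtering and poly(A)-signal annotation, computes per-gene effective
    3' UTR length and its Z-score profile, tests differential tandem-UTR
    usage between two conditions with the tandem UTR isoform switch index
    (TSI) and Benjamini-Hochberg FDR control, derives the relative usage of
    distal poly(A) sites (RUD) index from RNA-seq coverage, and couples
    3' UTR lengthening calls with expression changes through exact binomial
    trend tests. Ships a seed-deterministic simulator (gene models, genome
    sequence with mispriming decoys, tag tracks, coverage, expression) with
    full ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
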