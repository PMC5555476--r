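Package: guidescreen
Title: Design and Evaluation of Pooled CRISPR-SpCas9 Knockout Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis and design toolkit for pooled CRISPR/SpCas9 knockout
    screens. Computes normalized guide-level log2 fold-changes from readcount
    tables, gene-level essentiality Bayes Factors with a kernel-density
    classifier trained on reference essential and nonessential genes, and
    precision-recall / false-discovery machinery. Calls core essential genes
    across panels of screens, derives an empirical positional nucleotide
    delta-frequency score for 20-mer guides, and designs sequence-optimized
    genome-scale guide libraries with off-target-aware candidate
    classification and greedy exon-covering selection. Includes screen
    quality metrics (fraction of active guides, guide- and replicate-
    subsampling studies, control-population comparison) and a synthetic-data
    module that generates genomes, gene models, variant sets, and screen
    readcounts with known ground truth.
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
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    withr,
    optparse,
    vcfR
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
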