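Package: p53targets
Title: Identify Direct p53 Target Genes by Integrating ChIP-seq and Knockdown Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for calling direct transcriptional targets of
    chronically activated p53. Builds high-confidence consensus peak sets
    from replicated ChIP-seq peak calls, classifies peaks by genomic
    feature and CpG-island overlap, computes empirical-Bayes moderated
    differential expression posteriors for a p53-knockdown contrast,
    computes negative-binomial posteriors of TSS-local ChIP enrichment
    over input, and combines both arms into a joint per-gene posterior
    (B value) of being a direct p53 target. Includes a p53
    response-element PWM scanner with positional analysis around
    transcription start sites, and a synthetic-data generator with
    planted ground truth for end-to-end benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Biostrings,
    limma,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
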