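Package: subloc
Title: Multi-Label mRNA Subcellular Localization with Supervised
    Contrastive Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-stage multi-label prediction of mRNA subcellular
    localization from precomputed RNA language-model sequence embeddings.
    Stage one fine-tunes a residual convolution / self-attention encoder
    with a supervised contrastive loss whose positive pairs are mined by
    thresholding the Jaccard overlap of label sets; stage two trains a
    cross-attention multi-label decoder head over the frozen encoder with
    binary cross-entropy. Includes FASTA plus label-table ingestion with
    the standard preprocessing filters (duplicate collapse, non-standard
    nucleotide exclusion, end-preserving truncation, sequence-identity
    redundancy reduction), a label-structured synthetic data generator, a
    full panel of example-based and ranking-based multi-label metrics
    with per-compartment Matthews correlation, and a cross-validation
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    arrow,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
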