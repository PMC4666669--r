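Package: clipsv
Title: Split-Read and Soft-Clip Based Structural Variant Discovery,
    Genotyping and Association Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint multi-sample structural variant (SV) discovery from
    short-read alignments using shared soft-clip and split-read evidence.
    Breakpoint candidates are detected from pileups where three or more
    primary reads are clipped at the same base, refined with a clip-sequence
    consensus and local Smith-Waterman realignment, and paired with their
    partner breakpoint through supplementary (SA) and alternative (XA)
    alignment tags. Calls are genotyped under a bi-allelic mapping-quality
    likelihood model, typed (deletion, duplication, insertion, inversion)
    with a random forest over fourteen depth-normalised pileup attributes,
    and optionally scored for case-control allele-frequency differences with
    a binomial likelihood-ratio test. A seeded simulator generates synthetic
    references, truth SV sets and the alignment-level evidence they induce,
    together with a truth-interval benchmark harness for sensitivity and
    false-discovery-rate estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    stringr,
    ggplot2,
    generics,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    GenomeInfoDb,
    Rsamtools,
    randomForest,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    jsonlite,
    yaml,
    withr
Config/testthat/edition: 3
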