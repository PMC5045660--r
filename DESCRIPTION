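Package: bdptools
Title: Identification and Chromatin Analysis of Bidirectional Promoters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying bidirectional promoters (BDPs): identify
    head-to-head gene pairs from a GFF3 annotation and classify them by the
    distance between their transcription start sites; score promoter GC
    content, TATA-box presence and IUPAC motif occurrences; test motif
    overrepresentation against resampled unidirectional-promoter backgrounds
    with a Z statistic; classify gene-pair coexpression modes from
    multi-library FPKM matrices; build TSS-anchored, orientation-aware
    chromatin metaprofiles (histone marks, MNase nucleosome occupancy) with
    phased-nucleosome amplitude comparisons and two-sample Kolmogorov-Smirnov
    tests; and call drought-responsive gene pairs. Includes a synthetic-data
    generator that plants known pairs, motifs, correlations and nucleosome
    arrays so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    IRanges,
    S4Vectors,
    generics,
    GenomicRanges,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
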