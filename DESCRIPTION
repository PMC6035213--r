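Package: guidesites
Title: Guide RNA Target-Site Scanning and TSS-Window Enrichment Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide scanning for CRISPR guide RNA target sites
    (protospacer plus PAM), per-gene site-density statistics in
    TSS-anchored upstream windows, a Monte Carlo gene-set enrichment
    test over a protein-coding gene pool, ATAC-seq peak/site overlap
    comparison between sample groups, protospacer tiling of motif
    consensus sequences, and a synthetic-genome generator with planted
    ground truth so every statistic is verifiable at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    methods,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
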