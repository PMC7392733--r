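Package: pbscreen
Title: Analysis of piggyBac Transposon Insertional Mutagenesis Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical analysis of piggyBac (and other TTAA-targeting
    transposon) insertional mutagenesis screens in tumor cohorts: collapsing
    of quantitative insertion-site sequencing (QI-seq) reads into insertion
    sites, per-sample top-N filtering and cross-sample pooling, common
    insertion site (CIS) detection by multi-scale Gaussian kernel convolution
    with a Monte-Carlo null constrained to TTAA motif positions and
    Bonferroni-corrected significance, CIS-to-gene association with
    activating/disrupting insertion-pattern calls, two-tissue cohort
    comparison by Fisher's exact tests, multi-region clonality classification,
    and gene-transposon fusion-transcript integration. Includes a seeded
    synthetic-screen generator with ground-truth drivers so every stage of the
    pipeline can be exercised and benchmarked without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
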