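Package: clinetile
Title: Clinal Tiling-Array Differential Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting latitudinal (clinal)
    differential expression from genome tiling arrays. Maps tiling probes to a
    genome allowing one mismatch on either strand, labels them as exonic,
    intronic or intergenic, subtracts a windowed-percentile local background
    smoothed by local regression, applies an arsinh variance-stabilizing
    between-array calibration, computes empirical-Bayes moderated t-statistics
    for a North-versus-South contrast, aggregates probe-level p-values under
    short/medium/long window scenarios into called genes and intergenic
    regions, tests between-stage gene-list overlap with the hypergeometric
    distribution, scores functional-category enrichment by Wilcoxon rank sum
    with a gene-category permutation false discovery rate, and fits latitude
    regressions with externally Studentized residual outlier screening and
    delta-delta-Ct relative expression. Includes a synthetic-data generator
    that plants clinal effects so the whole pipeline is testable without
    array data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
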