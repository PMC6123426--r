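Package: lateralyzer
Title: Detection of Left-Right Transcriptomic Laterality and Developmental
    Asynchrony in Paired RNA-Seq Samples
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting subtle left-right differences in gene
    expression between paired samples of the same anatomical structure,
    and for asking whether such laterality reflects one side leading the
    other along a shared developmental trajectory. Implements
    precision-weighted paired differential expression with empirical-Bayes
    moderated t-statistics, from-scratch preranked weighted gene-set
    enrichment analysis (GSEA) with gene-set permutation nulls, a side-age
    t-value correlation statistic with an exhaustive left/right sign-flip
    permutation test, expression-based quality control (log2-CPM,
    expression filters, sex-marker checks, MDS outlier screening), Jaccard
    overlap summaries across structures, and a negative-binomial
    count simulator with known injected laterality for end-to-end
    verification.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
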