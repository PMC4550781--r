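Package: ploidymeth
Title: MSAP Methylation Profiling and qPCR Expression Analysis Across
    Plant Ploidy Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing cytosine methylation variation across a
    polyploid series from methylation-sensitive amplification polymorphism
    (MSAP) fingerprints, together with the cross-ploidy qRT-PCR expression
    arm that usually accompanies such studies. Classifies HpaII/MspI
    isoschizomer band patterns into non-, fully and hemi-methylated CCGG
    states, summarises per-sample methylation profiles, tests each sample
    against its ploidy-group mid-value with the pooled two-proportion U
    statistic, and correlates methylation level with ploidy. The expression
    arm ranks candidate reference genes by stability (pairwise-variation M
    values and an ANOVA-style variance score), chains segment-wise
    reference-gene normalizations across ploidy levels with an inter-run
    calibrator check, derives fold changes, and relates transcript
    abundance to flow-cytometric relative nuclear DNA content. A seeded
    synthetic-data module generates MSAP matrices, Ct tables and flow
    cytometry peaks with known structure so the whole pipeline is testable
    without instrument exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
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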