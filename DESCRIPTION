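Package: medipfrag
Title: DMR-Dependent Cell-Free DNA Fragmentation Analysis for cfMeDIP-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying the relationship between plasma
    cell-free DNA (cfDNA) methylation and fragmentation from cfMeDIP-seq
    paired Input/IP libraries. Reads, filters and deduplicates paired-end
    fragment records; computes short/long fragment-size statistics and
    genome-binned fragmentation profiles; calls differentially methylated
    10-kb windows with a negative-binomial Wald test; builds input-adjusted
    short-fragments-ratio profiles over hypomethylated windows; and scores
    samples against a healthy median baseline by Pearson correlation for
    cancer classification with ROC evaluation. Includes a mechanistic
    synthetic-cohort simulator (short fragments released from hypomethylated
    chromatin, depleted by 5mC immunoprecipitation) providing ground truth
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    Rsamtools,
    yaml
Config/testthat/edition: 3
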