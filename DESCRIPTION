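Package: distortnet
Title: Co-Occurrence Network Analysis of Cognitive Distortion Labels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Association mining and network psychometrics for multi-label
    annotations of cognitive distortions in text corpora. Computes
    observed/expected co-occurrence, lift and Bonferroni-corrected
    chi-square significance for all label pairs, a multiplicative triadic
    enrichment statistic (Integrated Significance Metric) over all
    three-way label combinations, weighted co-occurrence networks with
    centrality and topology metrics, bootstrap node-stability with dual
    core/exploratory thresholds, split-half and stratified reliability via
    quadratic assignment procedure (QAP) permutation tests, and
    misclassification noise-injection robustness sweeps. Includes a
    synthetic multi-label corpus generator with planted pairwise and
    triadic association structure for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    e1071,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
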