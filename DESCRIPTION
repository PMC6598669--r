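Package: pathreach
Title: Pathway and Reach Similarity Prioritisation of Cancer Driver Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mutation-frequency-free prioritisation of candidate cancer
    driver genes by resemblance to a reference set of known drivers. Each
    candidate is compared to the reference set through two binary similarity
    channels: shared biological-pathway membership (Jaccard similarity of
    pathway lists against a cut-off) and shared m-reach network-topology
    level (quantiles of the fraction of an interaction network reachable
    within m steps). The joint association of the two channels is tested per
    gene with Fisher's exact test over resampled reference subsets,
    Benjamini-Hochberg corrected, and summarised as a gene score in [0, 2]
    (lower is more driver-like). Includes readers for edge-list networks,
    GMT gene sets and plain gene lists, a synthetic-data generator with
    plantable driver signal, classifier evaluation (confusion metrics,
    Matthews correlation coefficient, ROC), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    igraph,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
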