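Package: replichrom
Title: Cell-Type-Specific Replication Timing, Chromatin and Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers replication-timing programs from fraction-sorted Repli-seq
    counts by Bayesian logistic regression (posterior logit timing scores,
    Bayes-factor tests for differential timing, nested region calling, LOESS
    smoothing, RT Z-scores), builds nucleosome-resolution histone-mark
    enrichment tracks from ChIC-ChIP fragment data by negative-binomial
    regression with Gaussian density smoothing and log2 fold enrichment,
    classifies pseudobulk single-cell expression (CPM on/off categories,
    cell-cycle reweighting, shrunken log fold changes with s-values), and
    integrates the three layers (gene-level replication-timing quadrants,
    enrichment at differential regions, cross-cell-type domain correlation).
    Ships a synthetic-data generator with planted ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
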