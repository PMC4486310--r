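Package: miRcouple
Title: Time-Series Integration of miRNA and mRNA Expression by
    Correlation and Target-Prediction Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to integrate paired microRNA and gene expression
    time-series profiles measured under a two-condition, multi-day design.
    The pipeline filters probes by intensity and inter-quartile range,
    calls per-day differential expression with an empirical-Bayes
    moderated t-statistic and Benjamini-Hochberg correction, screens every
    differentially expressed miRNA/probe pair by per-day Pearson
    correlation, forms the union of sequence-based target predictions over
    several databases, and intersects the two evidence streams into
    miRNA-gene couples. Couples are summarised as per-day bipartite
    regulatory networks with Freeman degree centralization, exported in
    SIF or GraphML form, and followed up by hypergeometric gene-set
    over-representation and PCA ordination. A synthetic-data generator
    with a ground-truth ledger of planted regulatory couples supports
    end-to-end benchmarking of precision and recall.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    fgsea,
    jsonlite,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
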