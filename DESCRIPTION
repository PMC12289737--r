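Package: integromir
Title: Joint Differential Expression and Integration of miRNA Ct Arrays
    and mRNA Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for two-group miRNA/mRNA expression
    studies on qPCR Ct arrays and two-colour microarrays. Provides Ct
    censoring and undetermined-value filtering, quantile normalization,
    Student's t and empirical-Bayes moderated t differential expression
    with Benjamini-Hochberg correction, 2^-ddCt relative quantification,
    hypergeometric gene-set over-representation against a custom
    expressed-gene background, inverse miRNA-target/mRNA intersection,
    directed regulatory-graph relation discovery (direct and one-
    intermediate paths) with chi-square direction testing, qPCR ddCt
    validation with cross-platform concordance, and a synthetic-data
    generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    igraph,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
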