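Package: zonage
Title: Zonation-Aware Analysis of Brain Endothelial Cell Aging and Its
    Pharmacological Reversal
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying arteriovenous zonation-dependent
    transcriptomic aging of brain endothelial cells from single-cell
    RNA-seq counts. Provides a truth-labelled negative-binomial
    simulator of 10x-style count data with planted zonation, aging and
    treatment-reversal structure; quality-control and marker-based
    primary cell typing; probabilistic EM assignment of endothelial
    cells to six arteriovenous subtypes with multi-seed consensus
    filtering; two-part (hurdle) differential expression with
    Benjamini-Hochberg adjustment; a treatment-reversal statistic with
    a constructed chance-level null and one-sided one-proportion
    z-test; hypergeometric disease-gene overrepresentation; and
    cross-species concordance against human bulk expression. A
    pipeline driver orchestrates all stages deterministically from a
    single seed.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
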