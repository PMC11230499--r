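Package: ppbclike
Title: Identification of PPBC-Like Cells in Mammary Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify a rare proliferative, regulon-positive
    ("PPBC-like") subpopulation in mammary gland single-cell RNA-seq by
    gene-signature feature-sum scoring with an adaptive half-of-maximum
    log2 cutoff, to annotate mammary epithelial cell types (luminal
    alveolar, luminal hormone-sensing, myoepithelial) from marker gene
    lists, to count p53-expressing cells, and to partition bulk RNA-seq
    differential-expression gene sets into exclusive and common Venn
    regions across lactation time points and genotypes. Includes a
    negative-binomial single-cell simulator with planted subpopulations
    and full ground-truth labels so the whole pipeline is testable
    end-to-end, plus replicate-level Welch t-tests, Benjamini-Hochberg
    adjustment, rank-sum per-gene differential expression, hierarchical
    ordering for heatmaps, and the modified ellipsoidal tumor-volume
    formula.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
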