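Package: ipscvar
Title: Variance Decomposition, Repeated-Measures Differential Expression and
    Study Design for hiPSC-Derived Transcriptomic Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical workflow for case/control transcriptomic studies of
    human induced pluripotent stem cell (hiPSC) derived neural progenitor
    cells and neurons, where each donor contributes several clonal lines and
    two culture cell types. Provides count filtering and trimmed-mean-of-
    M-values (TMM) normalization, expression-based sex inference, z-scoring
    of genes inside copy-number-variant regions, reference-based cell-type-
    composition scoring by non-negative least squares with residualization,
    per-gene linear mixed-model variance partitioning, permutation-based
    eQTL fold-enrichment curves, repeated-measures differential expression
    (precision weights, consensus intra-donor correlation, generalized least
    squares, empirical-Bayes moderation, Storey q-values), cross-cohort
    concordance, topological-overlap coexpression modules, an effective-
    sample-size study-design calculator, and a synthetic-cohort generator
    with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    lme4,
    pracma,
    ape,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    limma,
    statmod,
    withr,
    Matrix,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
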