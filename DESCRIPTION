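Package: scbin
Title: Binarized Single-Cell RNA-Seq Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for working with binarized (detection-pattern)
    representations of single-cell RNA-seq count matrices: bit-packed storage,
    per-cell concordance diagnostics between binary and normalized expression,
    linear embeddings (PCA and Jaccard similarity eigenmaps) with quality
    metrics, marker-detection cell-type annotation, detection-rate pseudobulk
    differential expression with a moderated-trend comparator and simulation
    benchmarks, per-gene zero-inflation model selection (Poisson, negative
    binomial, and their zero-inflated counterparts) with exact 2x2 enrichment
    inference, and recovery of relative expression from neighborhood detection
    patterns. Includes multi-sample and multi-cell-type synthetic data
    generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    cluster,
    MASS,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
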