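Package: pdjdsnmf
Title: Prior-Knowledge-Driven Joint Deep Semi-Nonnegative Matrix
    Factorization for Multi-Omics Integration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Joint decomposition of several omics expression matrices
    measured on the same samples into one shared sample-latent matrix and
    per-omics multilayer nonlinear (sigmoid-activated) coefficient
    hierarchies.  A protein-protein-interaction prior and per-omics
    graph-Laplacian penalties regularize the first-layer coefficients so
    that interacting or co-expressed features receive similar factor
    loadings.  Includes SVD-based initialization, a monotone adaptive
    gradient fitting loop, rank and penalty-grid model selection scored by
    reconstruction Pearson correlation, z-score co-expression module
    extraction, a planted-module synthetic data generator, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
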