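Package: biobombe
Title: Multi-Dimensionality Compression and Network-Projection
    Interpretation of Gene Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Compresses gene expression matrices with five algorithms
    (PCA, ICA, NMF, denoising and variational autoencoders) across a grid
    of latent dimensionalities and multiple random initializations, and
    interprets every compressed feature by projecting gene-set membership
    networks onto the learned weight matrices.  Significance of each
    gene-set score is assessed against a degree-preserving (XSwap)
    permutation null, yielding per-feature z-scores, Bonferroni-filtered
    top gene-set assignments, and gene-set coverage statistics.  Also
    provides SVCCA weight-matrix stability analysis, transfer of learned
    features to external expression data, trait enrichment tests, and
    elastic-net evaluation of compressed features, together with a
    synthetic-data generator with planted latent factors for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    data.table,
    glmnet,
    ica,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
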