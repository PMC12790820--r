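Package: plmx
Title: Explainable Partitioning of Protein Language Model Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Factors per-residue protein language model (PLM) embeddings into
    a 34-dimensional interpretable subspace of handcrafted biochemical
    features (three- and eight-state secondary structure, solvent
    accessibility, hydropathy, aromaticity and amino-acid identity) and a
    residual subspace trained adversarially, via a gradient reversal layer,
    to exclude those features while a decoder keeps the original embedding
    reconstructable. Includes DSSP and AlphaFold-style structure annotation,
    a synthetic-data generator with linear ground truth for validation,
    pooled gradient-boosting and convolutional downstream evaluation with
    bootstrap confidence intervals, and exact tree-SHAP attribution of
    pooled-embedding classifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
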