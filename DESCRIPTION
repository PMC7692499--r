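Package: gliotype
Title: Transcriptomic Subtyping of Gliomas by Density-Based Consensus
    Clustering and Ensemble Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised discovery and supervised calling of glioma
    transcriptome-profile subtypes from standardized gene expression
    matrices. Implements a density-based consensus clustering scheme
    (repeated UMAP embeddings of random gene subsets followed by DBSCAN,
    combined by plurality voting with an ambiguity rule), gene-signature
    construction via one-vs-rest differential expression and recursive
    feature elimination with linear support vector classifiers, an
    ensemble classifier of many small linear models combined by
    confidence-scored plurality voting, and downstream subtype
    characterization (mutation enrichment, survival stratification,
    tumor-purity comparison, and concordance with external
    classifications). Includes a synthetic-cohort generator with known
    subtype structure, purity dilution, mutations and survival for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    clue,
    e1071,
    jsonlite,
    matrixStats,
    mclust,
    stats,
    survival,
    tools,
    utils,
    uwot,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
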