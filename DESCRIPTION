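Package: grassmerge
Title: Multi-Omics Patient Subtyping by Grassmann Subspace Merging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for molecular subtyping of
    patients from multiple omics modalities. Per-modality patient similarity
    graphs (adaptive-bandwidth heat kernel) are converted to symmetric
    normalized Laplacians, embedded spectrally, and merged on the Grassmann
    manifold via a closed-form joint objective; cluster number is selected by
    silhouette over K-means partitions of the merged subspace. Downstream
    stages provide covariate-adjusted moderated-t differential expression
    with Benjamini-Hochberg control, hypergeometric over-representation
    analysis, and a phecode-based PheWAS logistic scan over eQTL genotypes.
    A synthetic-data generator with planted ground truth makes every stage
    testable without controlled-access cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    cluster,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    limma,
    fgsea,
    withr
Config/testthat/edition: 3
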