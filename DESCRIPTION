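Package: das28map
Title: Machine-Learning Re-Evaluation of the DAS28-CRP Score in Psoriatic Arthritis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Decomposes the DAS28-CRP composite disease-activity score into its
    58 individual items and re-evaluates their information content for psoriatic
    arthritis activity staging. Provides a seeded synthetic cohort generator,
    DAS28-CRP scoring and staging, unsupervised structure detection (PCA and
    emergent self-organizing maps with U-, P- and U*-matrices), density-guided
    generative augmentation of small clusters and outliers, random-forest
    permutation importance with computed ABC item categorization under nested
    Monte-Carlo cross-validation, and drug-therapy association statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
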