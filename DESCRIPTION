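Package: addressr
Title: Active-Learning-Guided Semi-Supervised Graph Embedding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonlinear dimensionality reduction for high-dimensional,
    sparsely labelled biomedical data. Implements unsupervised Graph
    Embedding (kappa-nearest-neighbour Gaussian affinity graph and the
    normalized-cuts generalized eigenproblem), its semi-supervised extension
    SSAGE (label-dependent affinity multipliers that attract same-class and
    repel different-class neighbours), and AdDReSS, an iterative scheme that
    couples SSAGE with active learning by SVM uncertainty sampling so that
    fewer expert labels are needed to obtain a class-separable embedding.
    Ships seeded generators for Swiss-Roll and high-dimensional two-class
    benchmarks, an experiment harness for label-reveal learning curves, and
    label-efficiency measures (random-forest accuracy, Silhouette Index,
    embedding variance, Raghavan efficiency, maximum query efficiency,
    maximum information gain).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    quadprog,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse
Config/testthat/edition: 3
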