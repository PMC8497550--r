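Package: lfmp
Title: Latent Factor Model and Projection for lncRNA-Disease Association
    Prediction
Version: 0.1.0
Authors@R:
    person("Repository", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Predicts lncRNA-disease associations without any known
    lncRNA-disease training pairs.  A preliminary score matrix is built
    by composing a lncRNA-miRNA adjacency matrix with a miRNA-disease
    adjacency matrix, densified with a regularized latent factor model
    trained by full-batch gradient descent, and refined by network
    consistency projection through integrated cosine/Jaccard similarity
    spaces with a weighted fusion.  Includes edge-list I/O, similarity
    kernels, LOOCV/k-fold ranking evaluation (AUC, AUPR), a planted
    partition tripartite network simulator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
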