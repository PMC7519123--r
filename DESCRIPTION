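Package: mtcov
Title: Community Detection in Attributed Multilayer Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mixed-membership community detection for directed, weighted,
    multilayer networks with categorical node attributes. Fits a Poisson
    tensor-factorization block model jointly with a multinomial attribute
    model by expectation-maximization, with a scaling parameter that trades
    off the network likelihood against the attribute likelihood. Includes a
    synthetic stochastic-block-model benchmark generator with planted
    communities and community-matched attributes, evaluation metrics for
    overlapping communities (matched F1/Jaccard, permutation-matched cosine
    similarity and L1 error), link-prediction AUC, attribute-prediction
    accuracy with random-probability and modal-frequency baselines,
    community attribute entropy, uniform and class-biased train/test
    masking, and k-fold cross-validation with grid search over the number
    of communities and the scaling parameter.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
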