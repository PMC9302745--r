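Package: daccord
Title: Concordance of Differential Abundance Calls on Relative Versus
    Absolute Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for benchmarking differential abundance
    testing on compositional sequence count data. Generates paired
    absolute and fixed-depth resampled ("observed") count matrices from a
    correlated log-normal/negative-binomial generative model, computes
    per-sample size factors under five renormalization strategies
    (total-count, trimmed mean of M-values, median-of-ratios,
    pooling-deconvolution, and sampling-fraction bias correction),
    tests features with a negative binomial GLM or a CLR Dirichlet
    Monte-Carlo test, and scores observed-data calls against an
    absolute-data oracle by sensitivity and specificity. Includes summary
    "signature" features of relative abundance data and random-forest
    meta-models that predict per-method accuracy from those signatures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    DESeq2,
    MASS,
    Matrix,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
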