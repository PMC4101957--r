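Package: msgsa
Title: Multivariate Self-Contained Gene Set Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Self-contained (subject-permutation) gene set analysis for
    expression studies with categorical or continuous phenotypes. Implements
    the one-sided OLS global test, Hotelling's T2 and Wilks' lambda MANOVA
    tests with a Schafer-Strimmer shrinkage covariance estimator, a
    random-forests out-of-bag permutation test, post hoc multiple comparisons
    among three or more conditions, Benjamini-Hochberg FDR and permutation
    family-wise error adjustment, diagnostic P-value and ranked-statistic
    plots, and a simulation harness for type I error and power studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    randomForest,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
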