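Package: sigwrap
Title: Significance-Based Wrapper Feature Selection for Binary Omics Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers the smallest feature subset that significantly
    contributes to the prediction accuracy of a binary classifier, for
    samples-by-features omics intensity tables (LC-HRMS peak tables,
    microarray expression matrices). Wraps three reference classifiers
    (PLS-DA with a NIPALS engine and automatic component selection,
    Random Forest, linear SVM) in a backward selection loop combining
    bootstrap resampling, classifier-specific feature ranking, permutation
    of candidate-subset intensities in out-of-bag test sets, and
    half-interval search, iterated to convergence. Ships the companion
    evaluation toolkit (balanced accuracy, Lustgarten signature stability,
    Q2Y permutation testing), comparator baselines (VIP filtering,
    recursive feature elimination), and synthetic/semi-synthetic data
    generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
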