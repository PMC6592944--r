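Package: rwov
Title: Relevant Word Order Vectorization for Clinical Free Text
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Vectorizes free-text clinical notes (e.g. breast-cancer pathology
    reports) by the signed reciprocal positional distance between a term of
    interest (such as a hormone-receptor mention) and the words that co-occur
    with it most frequently across a corpus. Includes the full surrounding
    pipeline: rule-based sentence splitting, tokenization, stop-word removal,
    symbol substitution and suffix stemming; relevant-vocabulary selection;
    n-gram/IDF and skip-gram embedding baseline vectorizations; classifier
    training (multilayer perceptron and support vector machine) with
    stratified cross-validation, per-class F1 and AUC, percentile bootstrap
    confidence intervals and DeLong comparison of correlated AUCs; and a
    template-based generator of labelled synthetic pathology reports for
    fully reproducible evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    graphics,
    stats,
    utils
Suggests:
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
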