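Package: episcreen
Title: Scoring Positive and Negative Epistasis from Quantitative Genetic
    Interaction Screens by Rank-One Matrix Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Transforms double-mutant fitness matrices from large-scale
    genetic interaction screens (SGA, GIM, E-MAP and similar designs) into
    interaction score matrices. Single-mutant fitness effects are estimated
    by rank-one matrix approximation under the multiplicative null model,
    using either a one-pass quantile-based decomposition (QMA) or
    alternating robust fitting with least-trimmed-squares regression (ARF).
    Between-screen technical variation is corrected with the query factor,
    gene pairs are scored with four scoring functions (minimum, maximum,
    product, scaled epistasis), and discrimination of the BioGRID genetic
    interaction categories (synthetic lethality, synthetic sick, phenotypic
    enhancement, phenotypic suppression) is evaluated with ROC curves,
    partial AUC and threshold metrics. A synthetic screen generator with
    planted interactions provides ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
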