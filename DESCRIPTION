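Package: metatransfer
Title: Meta-Learned Sample Weighting for Transfer Learning on Bioactivity Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Transfer learning for low-data compound activity prediction with a
    meta-learning front end that mitigates negative transfer. A meta-model learns
    per compound-target weights for source-domain pre-training through exact
    second-order meta-gradients (bilevel optimization with epoch-level gradient
    accumulation and Monte Carlo dropout weight sampling). Includes curation rules
    for Ki bioactivity tables (geometric-mean aggregation, potency thresholding,
    one-hot sequence encoding, leave-one-target-out source assembly, stratified
    low-data splits), a synthetic multi-task panel generator with a controllable
    transfer dial, and evaluation statistics (rank-based ROC-AUC, exact Wilcoxon
    signed-rank comparisons, negative transfer index).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    randomForest,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2,
    withr
Config/testthat/edition: 3
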