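Package: semkernels
Title: Semantic Kernels and Probabilistic Multiple Kernel Learning for
    Protein-Interaction Sentence Detection
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects sentences that describe protein-protein interactions
    using bag-of-words kernels smoothed with word co-occurrence structure
    learned from unlabelled text.  Implements the HAL (Hyperspace Analogue
    to Language) sliding-window co-occurrence model and the context-only
    BEAGLE random-indexing model, semantic smoothing of document-term
    matrices, cosine/Gaussian/polynomial kernels and their convex
    combinations, a variational-Bayes multinomial-probit multiple kernel
    learning classifier with inferred kernel weights, a repeated
    cross-validation harness with the variance-corrected resampled t-test,
    and a synthetic corpus generator with controlled synonym structure for
    end-to-end testing without external corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
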