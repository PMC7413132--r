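Package: crossdp
Title: Cross-Modal Data Programming for Weakly Supervised Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end cross-modal data programming: combine noisy,
    conflicting labeling functions written over an auxiliary modality
    (e.g. clinical text reports) into probabilistic training labels via
    an unsupervised generative label model, optionally distill those
    labels through an auxiliary-modality classifier for full coverage,
    and train a target-modality classifier with a noise-aware loss.
    Includes a synthetic paired-corpus generator with analytically known
    labeling-function statistics, ROC/DeLong evaluation, label-source
    ablations and data-scaling experiments, so every stage of the
    pipeline is verifiable at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
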