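Package: attnmi
Title: Motor-Imagery EEG Decoding with Sliding-Window Tokenization and
    Two-Stage Self-Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies four-class motor-imagery EEG trials with a compact
    convolutional feature extractor (temporal, depthwise spatial and local
    temporal convolutions with batch normalisation and average pooling),
    continuous and dilated sliding-window tokenization with trainable
    window-type tokens, and a two-stage (within-window then global)
    multi-head self-attention network trained by cross-entropy.  Ships a
    synthetic event-related-desynchronisation EEG generator, within- and
    between-subject cross-validation split builders, accuracy and Cohen's
    kappa metrics with confusion matrices, an ablation harness over the
    four architectural switches, feature export for embedding
    visualisation, and EDF/EDF+ readers and writers for epoching continuous
    recordings.  All forward and backward passes are implemented in plain
    matrix code; no external deep-learning runtime is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    tidyr,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
LinkingTo: Rcpp
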