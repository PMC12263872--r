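Package: swarmspeech
Title: Swarm-Intelligence Feature Selection and Deep Sequence Models for
    Speech-Based Depression Screening
Version: 0.1.0
Authors@R:
    person("swarmspeech", "developers", email = "swarmspeech@example.org",
           role = c("aut", "cre"))
Description: A reusable toolkit for speech-based binary screening pipelines:
    Mel-frequency cepstral coefficient (MFCC) extraction implemented from
    first principles, continuous-space Dragonfly, Firefly and Moth-Flame
    swarm optimizers behind a common minimization interface, wrapper feature
    selection with threshold binarization of swarm positions, a compact
    1D-CNN + LSTM binary classifier with manual backpropagation (no external
    deep-learning backend required), macro-averaged precision/recall/F1
    evaluation, and deterministic two-class synthetic audio and feature-table
    generators so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
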