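Package: deeframe
Title: Differential-Entropy EEG Features and Attention-Based Recurrent
    Networks for Emotion Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds three-dimensional differential-entropy feature tensors
    from multichannel EEG (baseline removal, non-overlapping windowing,
    Butterworth band decomposition into theta/alpha/beta/gamma bands,
    topographic projection of electrodes onto a sparse 9x9 grid), and
    trains an attention-based convolutional recurrent classifier for
    binary valence/arousal recognition. Includes an efficient-channel
    style frequency-band attention gate, a CNN-LSTM EEG branch with
    time-step self-attention, a CNN-TCN visual branch, and cross-modal
    knowledge distillation from the visual branch into the EEG branch via
    an L1 feature-matching loss. A synthetic-data module generates
    band-limited EEG with controllable class-dependent band power,
    pink-noise background, trial and baseline structure, ratings, visual
    feature sequences and frame clips, so the whole pipeline is testable
    without access-restricted datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
RoxygenNote: 7.3.3
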