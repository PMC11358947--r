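Package: eegdrive
Title: Decoding Driving Attention States from EEG Band-Power Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for detecting driver distraction states (focused,
    visual, auditory, cognitive) from multichannel EEG. Implements the
    full decoding chain: BrainVision/EDF/internal-format readers, mastoid
    re-referencing, band-pass filtering, downsampling, trial epoching and
    one-second windowing with amplitude-based artifact rejection; Welch
    power-spectral-density estimation and theta/alpha/beta band-feature
    construction; a gated recurrent unit implemented from first
    principles; a compact convolutional network for EEG (EEGNet) with a
    hand-written training loop; the composite three-branch GRU-EEGNet
    model with two-stage (freeze-then-train) optimisation; classical
    classifier baselines on band-power features; cross-validated
    evaluation metrics (accuracy, Cohen's kappa, macro F1) and a
    simulated online per-second detection loop. A synthetic EEG generator
    with 1/f background and state-dependent band-power effects provides
    reproducible data for all of it.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    kernlab,
    MASS,
    rpart,
    nnet,
    class,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
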