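Package: eegcomplete
Title: Virtual EEG Channel Completion with a Sparse-Attention Encoder-Decoder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Synthesizes "virtual" EEG acquisition channels from a small set
    of measured channels. A ProbSparse-attention encoder-decoder network with
    self-attention distilling is trained on windowed multichannel recordings
    to reconstruct the signal of an unmeasured or damaged electrode. The
    package covers the full workflow: montage geometry for the 22-electrode
    motor-imagery grid, recording input/output (delimited text and EDF),
    band-pass filtering and invertible per-channel normalization, windowed
    dataset construction, seeded training with Adam, stitched whole-recording
    completion, evaluation metrics (MSE, Pearson correlation), baseline and
    amplitude correction, an inverse-distance interpolation baseline,
    bad-channel flagging, cross-subject transfer evaluation, and a synthetic
    generator of spatially correlated band-limited EEG-like recordings so
    every stage runs without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
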