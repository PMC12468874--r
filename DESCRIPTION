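Package: pcgmixer
Title: Heart-Sound Classification from Spectrograms with a
    Residual-Attention Mixer Network and Intersection-Based Feature
    Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end classification of phonocardiogram (PCG)
    recordings into healthy and unhealthy classes. Recordings are read
    from WAV files, resampled to 2000 Hz, converted to fixed-size
    short-time Fourier transform spectrogram images, and passed through
    a lightweight deep network that trains a residual branch and a
    squeeze-and-excitation attention branch in parallel before an
    MLP-Mixer stage; deep features taken from the last ReLU layer are
    weighted by neighbourhood components analysis (NCA) and ReliefF,
    reduced to the intersection of the two top-x index sets, and
    classified with a polynomial-kernel support vector machine under
    repeated stratified cross-validation. A synthetic PCG generator
    with S1/S2 bursts and band-limited systolic murmurs makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    EBImage,
    png,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
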