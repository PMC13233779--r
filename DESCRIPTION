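Package: mrmgan
Title: Metacognitive Regularization for Adversarial EEG Generators
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generator-side regularization for adversarial models of epoched
    EEG. Implements a metacognitive regulation module consisting of three
    regularizers added to the generator objective of a Wasserstein GAN with
    gradient penalty: a time-domain term that matches three-point curvature
    profiles of real and generated traces through a binary cross-entropy,
    a frequency-domain term that matches normalized discrete-Fourier
    amplitude spectra, and a latent-space mode-seeking term driven by the
    ratio of cosine dissimilarities between generated outputs and their
    latent inputs. Ships reduced-scale WGAN-GP, conditional WGAN-GP and
    1-D convolutional (WaveGAN-style) trainers written in base R, Mode
    Score and sliced Wasserstein evaluation, Welch power spectral density
    and event-related-potential diagnostics, a trade-off weight selection
    rule, saturation curve fitting for augmentation experiments, an
    executable check of the latent regularizer's gradient-norm bound, and a
    synthetic P300 oddball data generator so the full pipeline runs without
    any external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    signal,
    jsonlite,
    yaml,
    rhdf5
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    minpack.lm,
    optparse
Config/testthat/edition: 3
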