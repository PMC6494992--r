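Package: ecggan
Title: Adversarial Synthesis of ECG Time Series with a BiLSTM Generator
    and a 1-D CNN Discriminator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates synthetic single-lead electrocardiogram (ECG) time
    series with a generative adversarial network whose generator is a
    two-layer bidirectional LSTM and whose discriminator is a
    one-dimensional convolutional network, alongside recurrent
    autoencoder and variational-autoencoder baselines.  Includes a reader
    and writer for MIT-BIH-style WFDB records (formats 212 and 16), a
    deterministic parameterised PQRST waveform simulator for fixture
    data, and the evaluation metrics used for generated signals: percent
    root mean square difference (PRD), root mean square error (RMSE) and
    the discrete Frechet distance.  All networks are implemented in pure
    R with analytic backpropagation and Adam optimisation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
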