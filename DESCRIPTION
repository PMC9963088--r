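Package: vcgrpeak
Title: R-Peak Detection in Multi-Lead ECG via 3D Vectorcardiogram Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects R-peaks in multi-lead electrocardiograms by converting the
    eight independent leads (I, II, V1-V6) to a 3D vectorcardiogram with the
    Kors regression transformation and segmenting it with a compact 1D
    encoder-decoder convolutional network (79,409 trainable parameters),
    trained and run entirely in R. Includes fixed-window segmentation with
    five-sample R-peak label masks, overlap-averaged inference with a
    consensus peak-extraction rule, tolerance-matched detection scoring
    (recall, precision, F1 at +/-75 ms), heart-rate-variability summaries,
    a Pan-Tompkins classical baseline, a deterministic multi-lead synthetic
    ECG generator with exact ground truth, and a minimal WFDB reader/writer
    so every stage is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    signal,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
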