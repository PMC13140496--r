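Package: respmech
Title: Neuromuscular and Neuromechanical Analysis of Respiratory EMG and
    Inspiratory Pressure Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing multi-channel respiratory
    electromyogram (EMG) and oesophageal pressure recordings from small
    rodents. Provides notch and Butterworth bandpass filtering with an
    automatic second-order-section stability fallback, rectified
    moving-average EMG envelopes, threshold-based breath segmentation,
    Welch power-spectral-density estimation with mean/median/maximum
    frequency and band power, Shannon, approximate and sample entropy,
    neural respiratory drive (NRD), neuromechanical efficiency (NME),
    tension-time index (TTI) and inspiratory drive-rate indices, and
    pressure-time analysis of sustained airway-occlusion efforts to task
    failure. Includes a seeded synthetic-recording generator with exact
    ground truth for every pipeline stage and a batch driver that turns
    directories of delimited text recordings into tidy summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
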