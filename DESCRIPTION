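Package: opmbeam
Title: Beamformer Simulation of On-Scalp and Conventional MEG Sensor Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for comparing on-scalp magnetometer arrays
    (such as optically-pumped magnetometer systems) with conventional
    SQUID-based helmet arrays for magnetoencephalography. Builds synthetic
    head and cortical surface geometry, constructs sensor arrays (a
    275-channel axial-gradiometer helmet, scalp-projected magnetometer
    arrays, and proportional EEG-layout arrays), computes dipole lead
    fields under a multiple local sphere head model with the Sarvas
    formula, simulates recordings with Gaussian dipole time courses and
    white sensor noise, reconstructs sources with a regularised LCMV
    beamformer, injects controlled forward-model error confined to the
    hyperplane orthogonal to the true lead field, and runs end-to-end
    experiments quantifying lead-field signal gain, reconstruction
    accuracy with and without interfering brain sources, sensitivity to
    forward-model error, and two-source spatial resolution as a function
    of channel count.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
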