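Package: spiketrans
Title: Spike Transmission Gain and Plasticity Analysis for Closed-Loop
    Optogenetic Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating effective connectivity between simultaneously
    recorded pyramidal cells and interneurons from spike trains, and for
    quantifying how that connectivity changes after closed-loop optogenetic
    stimulation. Implements cross-correlogram construction, hollowed-median
    baselines, deconvolution-based spike transmission gain (STG) estimation,
    a row-label permutation test for STG changes, closed-loop efficiency and
    light-response metrics, zero-lag synchrony effect sizes, converging-assembly
    (peer/non-peer) statistics, CCH-difference spike-timing features, and
    cross-validated SVM/SVR prediction of transmission changes. A synthetic
    closed-loop session generator with known ground truth supports parameter
    recovery and calibration studies end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    e1071,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
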