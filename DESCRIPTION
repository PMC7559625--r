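Package: alphagaze
Title: Coregistered EEG and Eye-Tracking Analysis of Internal Attention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for coregistered EEG and binocular eye-tracking
    studies of internally versus externally directed attention. Computes
    task-related alpha-band power (TRP) by complex demodulation, twelve
    oculometric parameters (pupil diameter, vergence angle, micro/saccades,
    blinks, fixations), coregistration-based artifact masking, trial and
    participant validity filtering, repeated-measures ANOVAs with partial
    eta-squared, and the 1-s-segment covariation of resting alpha power with
    eye behavior aggregated across subjects by Fisher's z. Includes a seeded
    generator of coupled synthetic EEG + eye-tracking recordings so the whole
    pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    jsonlite,
    readr,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    zoo,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
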