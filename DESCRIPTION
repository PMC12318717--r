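Package: burstnet
Title: Beta Bursts in Their Large-Scale Network Context for Resting-State
    Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for resting-state parcellated
    magnetoencephalography time courses: conventional motor-cortical
    beta-burst detection by Hilbert-envelope amplitude thresholding,
    time-delay-embedded hidden Markov model (TDE-HMM) inference of
    transient large-scale oscillatory networks, posterior-weighted
    multitaper state spectra and coherence, burst-network co-occurrence
    testing against a circular-shift null, segmentation of bursts into
    network-associated beta bursts (NABBs), and confound-adjusted group
    statistics with maximum-t-statistic and cluster-based permutation
    inference. Includes a synthetic cohort generator with known Markov
    state structure so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
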