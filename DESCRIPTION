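Package: subcortfp
Title: Cortico-Subcortical Connectivity Fingerprints from Probabilistic
    Tractography Counts and Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes threshold-based structural connectivity metrics (tract
    seed ratio and tract strength) from probabilistic-tractography
    sample-count volumes, resting-state ROI Pearson-correlation
    fingerprints, and a Bayesian comparison layer (JZS paired-t Bayes
    factors, g-prior mixed-model Bayes factors, 3xIQR outlier screening,
    evidence categorisation) for comparing the cortical connectivity
    fingerprints of the subthalamic nucleus and the striatum. Ships a
    synthetic phantom-cohort generator with known ground truth so the whole
    pipeline is testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
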