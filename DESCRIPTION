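Package: kneeae
Title: Acoustic Emission Candidate Biomarkers for Knee Osteoarthritis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for generating and evaluating acoustic-emission
    (AE) candidate biomarkers for knee osteoarthritis from sit-stand-sit movement
    tests: threshold-crossing hit detection on AE waveforms, goniometer-based
    movement-cycle segmentation into four kinematic quadrants, biomarker
    extraction (hit counts and principal-component scores of quadrant-wise 2D
    feature histograms), variance-component reproducibility models and covariate
    association models fitted by restricted maximum likelihood, and
    simulation-based trial power analysis. Includes a synthetic-data generator
    that emulates the repeated-measures study design so every stage is testable
    without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    MASS,
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
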