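Package: lesioncv
Title: Interlesional Texture Heterogeneity of Multi-Lesion CT by Coefficient of Variation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies interlesional, intra-patient heterogeneity in multi-lesion
    CT studies. Individual lesions are split out of integer label masks, filtered
    by equivalent-sphere diameter, and characterised by 75 second-order texture
    features from five matrix families (grey-level co-occurrence, run-length,
    size-zone, dependence and neighbouring grey-tone difference matrices).
    Heterogeneity is summarised per patient as the coefficient of variation of
    each feature across that patient's lesions, and a per-feature two-cohort
    screen (Welch t-test on patient-wise CVs) identifies features whose
    variability differs between cohorts. A synthetic two-cohort phantom
    generator with a controllable interlesional dispersion parameter provides
    ground truth for validating CV recovery and screen calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
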