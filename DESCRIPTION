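Package: tomotex
Title: Simulated Breast Tomosynthesis, Second-Order Texture Features, and
    Observer Performance
Version: 0.1.0
Authors@R:
    person("tomotex", "developers", email = "tomotex@example.org",
           role = c("aut", "cre"))
Description: An end-to-end simulation and analysis pipeline for studying how
    second-order image texture relates to lesion detection-localization
    performance in digital breast tomosynthesis (DBT). Provides a procedural
    voxelized compressed-breast phantom generator with controllable glandular
    fraction and spherical lesion insertion, a Siddon ray-tracing X-ray
    projector with a detector gain/blur/noise cascade, space-variant adaptive
    Wiener filtering of projections, Feldkamp-style filtered back projection
    with 3D Butterworth apodization and 1-mm slab extraction, lattice-ROI
    texture feature extraction (GLCM, NGTDM and RLM statistics), LROC study
    scoring with a parametric synthetic observer, and correlation of
    per-condition texture means with observer AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
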