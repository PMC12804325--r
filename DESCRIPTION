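Package: mamsim
Title: Monte Carlo Simulation of Measurement Errors in Minimum Ablative
    Margin Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates how technical measurement errors (image registration,
    segmentation, slice thickness) and biological effects (tissue shrinkage,
    microscopic satellite lesions) distort the minimum ablative margin (MAM)
    measured after thermal ablation of liver tumors. Synthetic 3D voxel
    phantoms of tumor and ablation zone are perturbed by statistically
    modeled error sources; signed Euclidean distance transforms yield the
    true and observed MAM per simulated case; and a logistic coverage model
    estimates the observed-margin threshold (A0) required for a 99%
    probability of complete microscopic tumor coverage, together with the
    reliability of the conventional 5-mm margin rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    ggplot2,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
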