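Package: vtloc
Title: Simulated Localization of Focal Ventricular Ectopy from ECGs and Device Electrograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A desk-scale computational pipeline for localizing focal ventricular
    ectopic sources (premature ventricular contractions and focal ventricular
    tachycardia) on a synthetic left-ventricular geometry. The package builds a
    truncated-ellipsoid LV mesh with rule-based fibers and universal ventricular
    coordinates, simulates paced beats with an anisotropic eikonal activation
    model, synthesizes 12-lead ECG and implanted-device electrogram traces
    through an infinite-medium lead-field forward model, encodes QRS complexes
    as 16x16 matrices, and trains small convolutional neural networks that
    localize the pacing site either through a segment-probability scheme
    weighted by AHA segment centers of gravity or through direct regression and
    classification in ventricular coordinates. Sensitivity sweeps over noise
    level and electrode placement are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
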