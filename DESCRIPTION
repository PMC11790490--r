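Package: zfstun
Title: Electrical Stunning Dosimetry, Tail Kinematics and Calcium Imaging
    Analysis for Larval Zebrafish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing electrical stunning of larval zebrafish:
    electric-field dosimetry (effective field, power and current density,
    adiabatic joule-heating simulation), mortality classification from
    behavioral death criteria with Wilson confidence intervals and pooled
    two-proportion z-tests, silhouette-based tail kinematics (median-filter
    preprocessing, morphological skeletonization, total tail angle, lateral
    displacement kymographs, tail-beat spectra), and calcium-imaging analyses
    (pixel-wise Welch power spectral density, GCaMP6f stimulus regressors,
    ROI tuning, cross-correlation matrices, autocorrelation functions).
    A synthetic-data generator produces silhouette videos, calcium movies,
    stimulus logs, mortality records and current traces with known ground
    truth so that every analysis stage is testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    EBImage,
    igraph,
    jsonlite,
    tiff,
    car,
    emmeans
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'zfstun-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'calcium-analysis.R'
    'electrical.R'
    'io.R'
    'mortality.R'
    'stimulus.R'
    'synth-calcium.R'
    'synth-tail.R'
    'tail-kinematics.R'
    'welch.R'
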