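Package: otloc
Title: Localizing the Outflow-Tract Origin of Ventricular Arrhythmia from the 12-Lead ECG
Version: 0.1.0
Authors@R:
    person("Analytics", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline that classifies the chamber of origin (right
    vs left ventricular outflow tract) of an outflow-tract premature
    ventricular complex from one sinus-rhythm beat and one ectopic beat of a
    standard 12-lead ECG. Includes wavelet (coif5/SURE) denoising, automated
    peak/valley morphology feature extraction with a ratio/difference
    expansion, conventional QRS measurements and twelve published
    localization criteria, gradient-boosted-tree classification with
    Shapley-value feature retention, ROC/DeLong/bootstrap evaluation
    statistics, and a fully parameterized synthetic 12-lead ECG generator
    used as the test substrate.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    data.table,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
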