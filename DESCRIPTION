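Package: motoradapt
Title: Modular Recurrent-Network Models of Rapid Motor-Cortical Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates rapid motor adaptation in a modular recurrent
    firing-rate network of the motor cortical pathway (an upstream area
    projecting to dorsal premotor cortex and on to primary motor cortex).
    Networks are trained by backpropagation-through-time with Adam on
    synthetic instructed-delay centre-out reaches, then re-trained under
    visuomotor rotations or cue reassociations with plasticity restricted
    to either upstream inputs or the local motor-cortical modules. The
    package quantifies the resulting changes in trial-averaged activity,
    neural covariance, connection weights and the participation-ratio
    dimensionality of weight changes, and includes robustness tests
    against simulated synaptic fluctuations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
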