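Package: retinamosaic
Title: Simulation and Inference for Fly Retinal Color Mosaics
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Column-wise stochastic lattice model of ommatidial color-fate
    choice in fly retinas. Generates binary mosaics spanning fully random
    (Drosophila-like), striped (dolichopodid-like) and intermediate
    patterns via a threshold-switch signaling relay with mistake
    propagation between adjacent columns; quantifies patterns with
    adjacent-column correlation statistics and phase-diagram scans; and
    recovers generative parameters by exact-likelihood grid search,
    including perturbation and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
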