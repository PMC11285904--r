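Package: abcland
Title: Likelihood-Free Calibration of Stochastic Stem Cell Models and
    Waddington Landscape Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calibrates a stochastic four-gene model of embryonic stem cell
    differentiation (Nanog, Oct4-Sox2, Fgf4, Gata6) against single-cell
    snapshot data using approximate Bayesian computation with sequential
    Monte Carlo (ABC-SMC). Snapshot ensembles are simulated exactly with the
    Gillespie algorithm or approximately with the chemical Langevin
    equation, and compared through distribution-level distances: unbiased
    maximum mean discrepancy, debiased entropic optimal transport (Sinkhorn
    divergence), and the Bhattacharyya distance via kernel density
    estimation. Posterior particle populations are analysed for sloppy and
    stiff parameter directions through a PCA variance decomposition, checked
    by posterior predictive simulation with a logit-pluripotency statistic,
    and used to reconstruct quasi-potential (Waddington) landscapes as the
    negative log density over gene-pair projections.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
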