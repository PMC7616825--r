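Package: mpcmr
Title: Time-Varying Causal Effects via Multi-Principal-Components Mendelian Randomization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the time-varying causal effect function of a longitudinal
    exposure on a scalar outcome using genetic variants as instrumental variables.
    Sparse, irregularly observed exposure trajectories are summarised by functional
    principal component analysis with conditional-expectation (PACE) score
    estimation; the principal component scores enter a multivariable Mendelian
    randomization model fitted by continuously-updating GMM, and the effect
    function is reconstructed on a chosen basis (eigenfunctions or polynomials).
    Weak-instrument-robust inference is provided through Kleibergen's Lagrange
    multiplier statistic, inverted over a parameter lattice to yield
    identification-robust confidence bands, together with conditional
    F-statistics, over-identification tests and a full simulation engine for
    method validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'basis.R'
    'diagnostics.R'
    'fpca.R'
    'gmm.R'
    'io.R'
    'mpcmr-package.R'
    'pipeline.R'
    'simulate.R'
    'smoothing.R'
    'weakiv.R'
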