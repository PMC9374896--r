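Package: spdstates
Title: Brain-State Detection and Spectral Signatures of Dynamic Functional
    Connectivity on the SPD Manifold
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing dynamic functional connectivity as
    trajectories of symmetric positive-definite (SPD) correlation matrices on
    the Riemannian manifold. Builds sliding-window Pearson connectivity from
    multichannel BOLD-like time series, removes inter-subject variation by
    parallel transport to a population Frechet mean, learns low-dimensional
    SPD representations with a geometric network of bilinear (BiMap) and
    eigenvalue-rectification (ReEig) layers trained by manifold gradient
    descent, detects brain-state changes with a mean-shift recurrence in the
    log-Euclidean chart, and characterises the detected states through
    eigen-spectra, system energy, eigenmode perturbation and subnetwork
    degree shares. Includes a block-modular synthetic BOLD generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    kernlab,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
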