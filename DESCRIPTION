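Package: biofilmemu
Title: Bayesian Surrogate Emulators for Biofilm Detachment Under
    Hydrodynamic Shear
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Surrogate modelling of biofilm deformation and detachment
    under hydrodynamic shear, replacing an expensive individual-based
    simulator with two chained Bayesian emulators: a Poisson log-linear
    regression with a quadratic exponential-mean, fitted by Metropolis
    MCMC, for the expected number of shear (detachment) events, and a
    dynamic linear model, fitted by Gibbs sampling with forward-filtering
    backward-sampling, for the log volume of detached clusters.  Includes
    a Latin-hypercube experimental design, a synthetic data generator
    with the statistical structure both emulators assume, time-resolved
    Sobol variance-based sensitivity analysis, and an end-to-end
    pipeline with train/test validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lhs,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
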