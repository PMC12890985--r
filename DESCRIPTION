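Package: memgle
Title: Non-Markovian Reaction-Coordinate Dynamics with Hierarchical Friction Memory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of one-dimensional protein
    reaction-coordinate dynamics under the generalized Langevin equation
    (GLE) with multiexponential friction memory. Provides Markovian
    embedding of exponential kernels, extraction of the memory kernel from
    discrete trajectories by Volterra inversion, multiexponential kernel
    fitting, hierarchical-ratio analysis and prediction of the finite-range
    subdiffusive mean-squared-displacement exponent, exact linear-system
    (matrix-exponential) MSD theory for free and harmonic potentials, mean
    first-passage-time profiles from first-first-passage events, and
    inversion of MFPT profiles to coordinate-dependent friction, together
    with Markovian comparator dynamics (constant and coordinate-dependent
    friction).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
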