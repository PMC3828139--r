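Package: photodyn
Title: Dynamical Adaptation Model of Photoreceptor Light Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of the dynamical adaptation (DA) model of
    photoreceptor light response: a feedforward nonlinear dynamical system in
    which two gamma-filtered copies of the light input jointly set the
    instantaneous gain and time scale of the membrane-potential response.
    Provides the model kernels and integrators (exponential Euler and the
    exact solution), closed-form limits (small flash, bright background,
    Weber-Fechner sensitivity, frequency-dependent gain, Gaussian-flicker
    statistics), deterministic and stochastic stimulus generators, a
    linear-nonlinear (LN) cascade baseline with instantaneous-gain
    diagnostics and circular-shift significance testing, and least-squares
    parameter estimation with sensitivity analysis.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
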