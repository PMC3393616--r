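Package: setdesign
Title: Set-Membership Experimental Design for Nonlinear ODE Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bounded-error (set-membership) experimental design for nonlinear
    continuous-time models of biological systems. Provides directed-rounding
    interval arithmetic, guaranteed enclosure of ODE solutions by interval
    Taylor series with mean-value-form propagation and matrix preconditioning,
    SIVIA set inversion for parameter and state estimation from interval
    measurements, construction of candidate measurements (time point, centre,
    range) from propagated uncertainty, fast evaluation of multi-measurement
    designs by parameter-set intersection, biologically interpretable design
    metrics (parameter volume, parameter-bound widths, state bounds), and a
    classical Fisher-information D-optimality comparator. Ships a
    Lotka-Volterra predator-prey case study that exercises the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
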