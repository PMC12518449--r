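Package: shiftpeaks
Title: Phenotype-Structured Populations Under Shifting Fitness Optima
Version: 0.1.0
Authors@R:
    person("shiftpeaks", "developers", email = "shiftpeaks@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the long-time behaviour of a non-local
    parabolic (Lotka-Volterra selection-mutation) model of an asexual
    population whose fitness landscape carries one or two moving optima.
    Provides compactly supported polynomial-bump fitness landscapes with
    linear shift, an explicit finite-difference solver for the non-local
    PDE on a truncated trait domain, an asymptotic-preserving scheme for
    the constrained Hamilton-Jacobi formulation (including the
    zero-mutation limit scheme with its scalar root-finding step),
    discretized principal-eigenvalue machinery for the associated
    stationary Sturm-Liouville problems (Dirichlet balls, Liouville
    similarity transform, extinction/persistence classification), the
    eikonal representation formula for the limiting phase, and
    diagnostics that compare simulated concentration locations and
    limiting total mass against the spectral predictions (lagged optima,
    shallowest-peak selection).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
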