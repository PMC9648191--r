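Package: rfepr
Title: Restrain-FEP-Release Conformational Free Energy on Toy Torsional Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Alchemical calculation of conformational free-energy differences
    between two torsional states (anti vs syn about a glycosyl-like bond) by the
    restrain - free-energy-perturbation - release (R-FEP-R) staging on a dual
    topology with soft-core decoupling. Provides a synthetic toy-system
    generator with exact quadrature reference free energies, a Metropolis Monte
    Carlo sampler over lambda states, multistate Bennett acceptance ratio
    (MBAR), Bennett acceptance ratio (BAR) and exponential-averaging
    estimators with asymptotic uncertainties, phase-space overlap matrices,
    forward/reverse convergence diagnostics, Boltzmann population conversion,
    and readers/writers for dH/dlambda tables in GROMACS-dialect XVG and CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
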