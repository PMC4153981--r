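Package: cmexact
Title: Exact Time-Dependent Solutions of the Chemical Master Equation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form, time-dependent probability distributions for
    stochastic chemical reaction networks. Solves the chemical master
    equation (CME) of general finite-state networks through a spectral
    solution built from eigenvalues and cofactor (adjugate) matrices, and
    monomolecular (first-order) networks exactly through Poisson and
    Multinomial convolution formulas, including marginal distributions for
    selected species and equilibrium formulas for unbranched chain and ring
    topologies. Tridiagonal rate matrices are handled with the Usmani
    inverse/adjugate recursion. A Gillespie direct-method stochastic
    simulator and an empirical-versus-analytical error metric are included
    for cross-validation. Case studies: a protein autoactivation mechanism,
    randomized monomolecular chains, and a four-state ryanodine-receptor
    calcium gating ring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
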