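Package: delaychain
Title: Exact Reduction of Monomolecular Reaction Chains into Delayed Reactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact model reduction of bi-directional monomolecular reaction
    chains (with bypass, degradation and synthesis reactions) into delayed
    reaction models. First-arrival and first-return time distributions of the
    lumped intermediates are derived in closed form (hypoexponential stage
    form for tridiagonal chains, eigenvalue/residue form with minor-based
    coefficients for chains with bypasses) with a matrix-exponential numeric
    fallback, and the reduced models are simulated exactly with a rejection
    delay stochastic simulation algorithm (DSSA). Includes a direct-method
    SSA, single-walker first-passage oracles and ensemble comparison
    statistics that make the distributional equivalence of full and abridged
    models testable, plus worked glycolysis and kinetic-proofreading systems.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
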