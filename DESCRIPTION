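Package: chiralnet
Title: Stability Analysis of Pseudochiral Reaction Networks for
    Mirror-Symmetry Breaking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for deciding whether a mass-action chemical reaction
    network that models absolute asymmetric synthesis admits spontaneous
    mirror-symmetry breaking (SMSB), and for sampling the racemic steady
    states that trigger homochiral dynamics.  The package parses a plain-text
    reaction-network description, verifies pseudochirality (the invariance of
    the network under the exchange of every enantiomeric pair), builds the
    racemic Jacobian and its enantiomeric coupling blocks, and applies
    stoichiometric network analysis: exact enumeration of the extreme
    currents of the steady-state flux cone, Clarke's convex coordinates, and
    a sampling heuristic over the signed characteristic-polynomial
    coefficients of the reduced stability matrix.  Sampled states are
    back-mapped to explicit concentrations and rate constants and confirmed
    both by Routh-Hurwitz/eigenvalue analysis and by stiff ODE integration
    of the perturbed racemic state.  Classical benchmark models of biological
    homochirality (Frank, Calvin, the Hochberg-Ribo replicator, APED,
    Iwamoto) ship as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
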