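Package: eesnet
Title: Effective Empirical Subnetworks for Gene Influence Networks
Version: 0.1.0
Authors@R:
    person("eesnet", "developers", email = "eesnet@example.org",
           role = c("aut", "cre"))
Description: Fits a low-dimensional affine model (the effective empirical
    subnetwork, EES) of a gene influence network's steady-state surface
    from wildtype and single-knockout expression profiles, predicts
    expression in unseen mutants such as double knockouts, and computes
    how to steer the network equilibrium toward a prescribed expression
    state by clamping a small set of controllable genes.  Includes a
    synthetic clustered Hill-function network simulator used as ground
    truth, a clamped steady-state solver with viability classification,
    replicate-aware one-sample t-test validation against measured mutant
    expression, and tabular/JSON input-output with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    jsonlite,
    stats,
    utils,
    graphics,
    withr,
    yaml
Suggests:
    numDeriv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
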