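Package: pnthelix
Title: Steered Self-Assembly and Chirality Analysis of Diphenylalanine Peptide Nanotubes
Version: 0.1.0
Authors@R:
    person("pnthelix", "developers", email = "pnthelix@example.org", role = c("aut", "cre"))
Description: Builds linear chains and parametric helices of zwitterionic
    diphenylalanine (FF) dipeptides of either chirality, drives them into
    helical nanotube conformations with a reduced-model steered molecular
    dynamics engine (staged Hooke-spring scaffolds under a collisional
    thermostat), and quantifies the handedness of the result with two
    mixed-product chirality indices: one over support vectors joining
    consecutive alpha carbons and one over per-unit dipole moments computed
    from partial charges about each unit's centre of mass. Includes axis
    fitting, radial statistics, cylindrical surface maps, reflection-free
    pairwise superposition, many-run sign statistics, and a command-line
    interface for reproducible batch experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
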