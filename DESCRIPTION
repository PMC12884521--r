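Package: pocketconf
Title: Ligand-in-Pocket Conformer Analysis with Two-Layer Energy
    Combination and Noncovalent Interaction Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing a flexible ligand inside a rigid receptor
    pocket: distance-based active-site extraction from PDB structures with
    rule-based protonation and terminal capping, systematic conformer
    enumeration by dihedral scanning and rigid translation, clash filtering,
    constrained local minimisation against a pluggable energy backend
    (a Dreiding-style nonbonded force field ships as the default surrogate),
    two-layer ONIOM-style energy extrapolation, Boltzmann conformer
    populations, binding-energy decomposition and the dissociation-constant
    bridge, promolecular noncovalent-interaction (NCI) analysis via the
    reduced density gradient and sign(lambda2)*rho, geometric hydrogen-bond
    tables, and UV-vis spectral post-processing of electronic transition
    tables. A seeded synthetic-data module generates toy pocket-ligand
    complexes with planted energy minima so every stage is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
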