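Package: chalcogenmm
Title: Sigma-Hole Pseudoatom Force Fields for Chalcogen Bonding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building molecular-mechanics parameter sets that model
    the sigma-hole of chalcogen atoms with a massless, positively charged
    virtual site. Fits harmonic bond/angle constants and periodic torsion
    series to relaxed potential-energy-scan data, derives restrained
    electrostatic potential (RESP) point charges on grids that include a
    manually inserted pseudoatom site, constructs the fixed-distance
    (2fd-style) virtual-site geometry, evaluates and minimizes classical
    energies of small gas-phase complexes, measures chalcogen-bond geometry,
    and writes GROMACS-dialect topologies. Ships a deterministic synthetic
    fixture (an ebselen-like selenium core) so the whole workflow runs
    without any quantum-chemistry input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
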