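Package: radtunnel
Title: Tunneling-Corrected Barriers and Active-Site Geometry for Radical
    C-C Bond Scission
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale analysis of hydrogen-atom-transfer tunneling and
    active-site geometry in radical SAM lyases. Implements the Eckart and
    Bell quantum tunneling corrections to hydrogen-abstraction barriers
    (transmission coefficients, effective barriers, imaginary-frequency
    inversion, kinetic isotope effects), parsing and analysis of reaction
    energy profiles and bond/dihedral scan curves (stationary points,
    Eckart fits, migrating-hydrogen transfer distances, scission-completion
    classification), Newman-projection regiospecificity assessment,
    polar-contact censuses with square-pyramidal typing, trimmed Kabsch
    superposition, side-chain rotamer deltas, and grid-based cavity and
    channel mapping at a given probe radius. Seeded synthetic-data
    generators with known ground truth emulate every input class so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
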