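Package: sirasfx
Title: SIRAS Phasing Pipeline for Serial Femtosecond Crystallography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for de novo phasing of serial
    femtosecond crystallography (SFX) data by single isomorphous replacement
    with anomalous scattering (SIRAS). Provides orthorhombic unit-cell and
    space-group bookkeeping, structure-factor computation with anomalous
    corrections, Monte-Carlo merging of per-snapshot partial intensities with
    the standard half-dataset quality statistics (R_split, CC_1/2, CC_ano),
    difference-Patterson heavy-atom location via Harker-section symmetry
    minimum functions, Blow-Crick probabilistic phasing in SIR, SAD and SIRAS
    modes with solvent flattening, and titration experiments that measure how
    many snapshots each phasing mode needs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
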