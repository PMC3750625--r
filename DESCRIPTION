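Package: xldock
Title: Crosslink-Guided Rigid-Body Docking of Protein Homodimers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models protein homodimer arrangements from chemical
    crosslinking mass spectrometry (XL-MS) data. Enumerates theoretical
    crosslinked peptide products (dead-end, looplink, inter-peptide) for
    amine-reactive linkers such as BS3, matches them against peak lists,
    validates candidate crosslinks against monomer structures by
    C-beta distance, generates rigid-body dimer poses by FFT-accelerated
    shape-complementarity correlation with an electrostatic filter,
    selects poses compatible with crosslink distance restraints, refines
    the rigid-body placement, and characterizes the resulting interface
    (buried surface area, interface residues, parallel/antiparallel
    orientation). Includes a seeded synthetic-data generator producing
    ground-truthed toy monomers, planted dimers and peak lists so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
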