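Package: iontoggle
Title: Sodium Binding Pathways and the Trp6.48 Rotamer Toggle from Langevin
    Models and Well-Tempered Metadynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for characterizing ion binding in a
    transmembrane channel coupled to a side-chain rotamer switch. Provides a
    four-degree-of-freedom overdamped Langevin generator on a constructed
    channel potential with three binding sites and a switch-coupled periodic
    rotamer coordinate; well-tempered metadynamics over the (z, chi2)
    collective-variable space with replica-averaged free-energy surfaces and
    per-cell error maps; minimax-path barrier and basin extraction; 3D ion
    occupancy grids converted to chemical-potential maps relative to a bulk
    concentration; anchor contact-frequency statistics; dihedral, rotamer and
    superposition (Kabsch RMSD) operators; and deterministic TSV/XYZ/OpenDX/
    YAML readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
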