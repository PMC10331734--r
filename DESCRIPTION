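Package: xfpchromo
Title: Force-Field Parameters and Charge-Fitting Tools for
    Fluorescent-Protein Chromophores
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assembles and emits the AMBER-compatible parameter set for
    seven fluorescent-protein chromophores (EGFP, EBFP in HID and HIE
    forms, ECFP, EYFP, DsRed, mCherry) as a typed force-field
    modification (frcmod) database with section-faithful serialization
    and wildcard-aware lookup.  Performs constrained two-stage
    restrained electrostatic potential (RESP) charge fitting under
    free-fit, cap-fix, and amide-fix constraint schemes, including the
    proline-like amino-terminus variant used for DsRed and mCherry.
    Scores candidate atom-type models against reference geometries by
    bond-length RMSD, computes internal coordinates and Kabsch
    superpositions, and validates chromophore behaviour by comparing
    Gaussian summaries of internal-coordinate distributions between
    trajectories.  Includes seedable synthetic-fixture generators for
    ESP grids, capped topologies, perturbed geometries, and
    autocorrelated angle series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
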