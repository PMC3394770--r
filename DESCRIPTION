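Package: ipolectin
Title: Structural and Thermodynamic Characterization of a Tetrameric
    Jacalin-Related Lectin
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the computational characterization of ipomoelin
    (IPO), a wound-inducible jacalin-related lectin of sweet potato, and
    of beta-prism lectins generally: fixed-column PDB reading and writing
    with unit-cell metadata, Matthews coefficient and solvent-content
    estimation, crystallographic symmetry expansion and contact-based
    oligomer assembly, Shrake-Rupley solvent-accessible surface area and
    buried-interface analysis, heavy-atom hydrogen-bond, methyl-pi and
    metal-coordination detection in carbohydrate binding pockets,
    single-site (Wiseman) isothermal titration calorimetry simulation and
    fitting with full thermodynamic decomposition, and size-exclusion
    molecular-weight calibration with oligomeric-state calling. A
    synthetic-data module generates toy crystals, titration curves and
    calibration standards with known ground truth so the whole pipeline
    is testable without external coordinate files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
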