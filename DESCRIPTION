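Package: chiroswim
Title: Chiral Swimming Path Simulation and Motility Analysis for Trypanosomatids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how chiral cell shape confers directional
    swimming at low Reynolds number, built around trypanosomatid parasites.
    Provides closed-form helical swimming-path geometry (curvature, torsion,
    directionality), anisotropic Brownian diffusion coefficients for a
    prolate-spheroid cell with Perrin friction factors, a Brownian-dynamics
    swimmer simulator with chirality-driven longitudinal rotation, a
    synthetic dark-field videomicrograph renderer with depth-dependent
    detectability, a cell detection/linking/persistence tracking pipeline,
    an analytical cell-shape and flagellar-beat model with kymograph fitting
    and effective hydrodynamic shape reconstruction, and a resistive-force
    (slender-body) calculation of the axial torque generated by chiral cell
    shapes under flow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    yaml,
    jsonlite,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
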