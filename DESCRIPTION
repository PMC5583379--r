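Package: mreitire
Title: Predicting Irreversible Electroporation Ablation Zones from
    Magnetic Resonance Current-Density Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs in-plane electric field distributions established
    during irreversible electroporation (IRE) from current-density-imaging
    (CDI) data using the iterative J-substitution MREIT algorithm, converts
    the field to cell-death probability with the Peleg-Fermi survival model,
    extracts predicted ablation areas at chosen probability levels, and
    scores agreement between predicted and reference ablation areas with
    linear regression and Bland-Altman analysis. A synthetic phantom
    generator and a forward simulator (finite-difference potential solver,
    two-dimensional Biot-Savart magnetic flux synthesis, CDI phase encoding)
    make the whole measurement-and-reconstruction chain testable without
    scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
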