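Package: twachp
Title: Thin-Walled Area Prediction for Cerebral Aneurysms from Normalized
    Hemodynamics and Intraoperative Color Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processes pulsatile wall-shear-stress fields on aneurysm
    surface meshes into an oscillatory shear index (OSI), sac-normalized wall
    shear stress, and a weighted combined hemodynamic parameter (CHP) that
    flags candidate thin-walled areas; quantifies redness of intraoperative
    images against a normal-vessel reference with CIEDE2000 color differences
    and a redness-projected modified metric; and compares the two predictions
    with a Shapiro-Wilk-gated two-group testing protocol. Includes a
    synthetic-data generator producing pulsatile wall fields with a planted
    low-shear, direction-reversing patch and matched dome images with a
    co-located reddish patch, so the whole pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    farver,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
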