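Package: crtarget
Title: CT-Guided Target Selection for Cardiac Resynchronization Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale analysis pipeline for CT-guided left-ventricular (LV)
    lead targeting in cardiac resynchronization therapy (CRT): endocardial
    wall-motion tracking on dynamic LV surface meshes, regional strain and
    local area change on the AHA 16/17-segment model, time-to-peak mechanical
    activation, scar-exclusion target-segment selection, coronary-vein
    subtension matching, C-arm projection overlays, and acute hemodynamic
    response (dP/dt_max) and remodeling statistics. Includes a fully seeded
    synthetic generator (contracting prolate-spheroid LV, venous tree,
    hemodynamic cohorts) so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
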