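Package: prostacoreg
Title: Co-Registration of Micro-Ultrasound and MRI with Whole-Mount Pathology
Version: 0.1.0
Authors@R: person("Prostacoreg", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to map para-sagittal micro-ultrasound fan sweeps, axial MRI,
    and axial whole-mount pathology slides of the prostate into a common
    coordinate frame. Implements rotational fan-sweep volume reconstruction,
    rigid initialization plus landmark thin-plate-spline registration with
    target registration error (TRE) assessment, 2D capsule-based slice
    registration with transition-zone Dice scoring, annotation point-cloud
    transport with DBSCAN region-of-interest extraction, and pixel-, slide-,
    and patient-level concordance metrics. A deterministic digital-prostate
    phantom simulates all three acquisitions with known ground truth so every
    stage is testable end-to-end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse,
    knitr
Config/testthat/edition: 3
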