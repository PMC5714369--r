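Package: arcqa
Title: Cylindrical Diode-Array Quality Assurance for VMAT Delivery Verification
Version: 0.1.0
Authors@R: person("arcqa", "maintainers", email = "arcqa@example.org", role = c("aut", "cre"))
Description: Tools for patient-specific quality assurance of volumetric-modulated
    arc therapy (VMAT) deliveries with a virtual cylindrical diode-array phantom.
    Models the spiral diode layout and annular acrylic phantom, reads and writes
    DICOM-RT Plan and Dose objects, decomposes arc control points into
    monitor-unit weighted subfields with a multileaf-collimator transmission
    model, computes dose with a tissue-maximum-ratio ray engine (effective path
    length and inverse-square corrections), evaluates agreement with the
    gamma index including criteria sweeps and cylindrical wrap-around, and runs
    end-to-end sensitivity studies for detector angular response and rigid setup
    misalignment on synthetic fixtures.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
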