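Package: eptplan
Title: Treatment Planning for Electroporation-Based Therapies
Version: 0.1.0
Authors@R:
    person("EPT", "Maintainers", email = "maintainers@eptplan.org", role = c("aut", "cre"))
Description: Scriptable toolkit for planning electrochemotherapy (ECT) and
    irreversible electroporation (IRE) treatments of deep-seated tumors.
    Reads DICOM series, segments target anatomy (liver on CT and MRI,
    hepatic vessels via multiscale Frangi vesselness, bone, canine brain),
    converts masks to editable per-slice contours with relevance-based
    point reduction, places parallel needle-electrode arrays from a
    two-point trajectory, solves the nonlinear conduction equation with
    field-dependent tissue conductivity on the voxel grid, derives
    cumulative coverage curves and per-pair voltage plans, and renders a
    treatment report. Includes synthetic phantom generators with ground
    truth masks so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
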