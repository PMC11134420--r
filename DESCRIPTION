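Package: probereg
Title: Probe Coregistration and Spatial Error Metrics for Infrared 3D Head Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for spatial registration of neuroimaging probes (fNIRS
    optodes, EEG electrodes) labeled on infrared 3D head scans. Parses MeshLab
    PickPoints (.pp) files and marker CSV tables, builds anatomical head frames
    from the nasion/LPA/RPA fiducials, performs closed-form rigid (optionally
    scaled) control-point registration onto repeat scans, MRI-derived
    references, or a bundled idealized 10-05 template montage, and computes
    four scan-validation error metrics: between-subject cap-fixation
    variability, scan-versus-MRI accuracy, scan-rescan reproducibility, and
    inter-optode channel distances, each summarized per optode and pooled.
    Includes a synthetic-cohort simulator (ellipsoidal scalps, a 25-optode /
    24-channel layout at fixed 30 mm spacing, cap-placement jitter and
    digitization noise), an OBJ head-mesh defacing module that preserves the
    anatomical landmarks, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
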