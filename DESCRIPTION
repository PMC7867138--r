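Package: mfce
Title: Minimum Foot Clearance Estimation from Calibrated Sagittal-Plane Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline analysis pipeline for estimating per-stride minimum foot
    clearance (MFC), in millimetres, from sagittal-plane video of a
    pedestrian's feet recorded next to a walkway. Includes laser-dot metric
    calibration (two parallel laser beams of known physical separation
    projected onto the lower leg define a pixel-to-millimetre scale),
    pluggable footwear instance segmentation with a four-state frame
    classifier and chamfer-style occlusion recovery for double-support
    frames, stride segmentation from swing-foot motion, quintic trajectory
    fitting with analytic local-minimum extraction, a seeded synthetic scene
    generator with exact ground truth, and evaluation metrics (mask IOU,
    bottom-edge RMS, inter-rater RMS, Bland-Altman agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
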