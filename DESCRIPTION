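Package: relmo3d
Title: Three-Dimensional Relative Motion Assessment for Human-Exoskeleton Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the residual motion between a user's thigh and the
    link of a lower-limb exoskeleton from labeled optical motion-capture
    trajectories. Builds anatomical and device local coordinate frames from
    marker positions, computes the frame-by-frame relative rotation matrix
    and its Euler decomposition (RotX frontal, RotY transverse, RotZ
    sagittal), segments walking trials into gait cycles from heel-strike
    events, and reports orientation-difference statistics: overall means,
    per-cycle rotation ranges (mean, SD, coefficient of variation),
    sub-phase rotation differences, and inter-cycle cross-correlation
    consistency. Includes a C3D/CSV trajectory reader with explicit gap
    handling and a synthetic gait generator with prescribed relative motion
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
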