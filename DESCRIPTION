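Package: htmphase
Title: Phase-Specific Biomechanical Analysis of Hand-to-Mouth Movements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phase-specific biomechanical characterization of
    hand-to-mouth (HTM) upper-limb movements from multichannel surface EMG and
    wrist/joint kinematics. Implements the full chain from raw signals to
    group-level inference: EMG linear envelopes and activation dynamics,
    Hill-type muscle force and torque estimation over a planar two-link arm,
    kinematic segmentation of the movement into four subphases, phase-windowed
    mechanical work, spectral arc length (SPARC) torque smoothness, a
    torque-based co-contraction index (TCCI), normality-routed group
    comparisons with false-discovery-rate control, severity-score correlations,
    and cross-validated stroke-versus-healthy classification with five
    standard classifiers. A seeded synthetic-cohort generator emulates healthy
    and stroke-like trials with known ground truth so the entire pipeline is
    reproducible without clinical recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    e1071,
    jsonlite,
    MASS,
    pracma,
    signal,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
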