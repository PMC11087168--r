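Package: planperturb
Title: Beam-Model Sensitivity and Complexity-Metric Analysis for IMRT/VMAT Plans
Version: 0.1.0
Authors@R: person("planperturb", "developers", role = c("aut", "cre"),
    email = "planperturb@example.org")
Description: Tools for studying how treatment-planning-system (TPS) beam-model
    parameter errors propagate into delivered-dose errors for IMRT and VMAT
    plans, and which aperture complexity metrics best predict that
    sensitivity. Provides a domain model for multi-leaf collimator (MLC)
    plans with minimal DICOM-RT Plan and JSON input/output, a seeded
    synthetic cohort generator spanning five anatomical-site presets, the 18
    standard plan complexity metrics (modulation complexity score, tongue and
    groove index, mean MLC gap, and others), a 2D aperture-fluence dose
    surrogate that applies ten perturbable beam-model parameters at community
    percentile values, and a study pipeline that tabulates dose-proxy
    deviations, filters parameters, regresses deviations on complexity
    scores, ranks metrics and derives complexity action thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
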