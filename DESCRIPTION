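Package: fpclamp
Title: Self-Paced Treadmill Speed and Propulsive-Force Clamp Experiments
Version: 0.1.0
Authors@R: person("fpclamp", "maintainers", email = "fpclamp@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of treadmill "clamp" walking
    experiments that prescribe either a fixed belt speed or a peak
    propulsive force target via biofeedback on a self-paced treadmill
    driven by a dead-zone proportional controller. Generates calibrated
    synthetic cohorts as raw ground-reaction-force, center-of-pressure,
    heel-marker and breath-by-breath time series; extracts gait events,
    propulsive and braking peaks, stride metrics, net metabolic power and
    cost of transport; and runs the pooled correlation and repeated-
    measures ANOVA analysis linking propulsive force, walking speed and
    walking economy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
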