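Package: splitbeltsim
Title: Cerebellum-Augmented Reflex Control of Split-Belt Gait Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulator and analysis toolkit for locomotor adaptation on a
    split-belt treadmill under a hierarchical control model. A spinal layer
    is a reflex-based gait controller with a five-phase state machine and a
    timed swing-initiation trigger; a supraspinal (cerebellar) layer keeps
    an internal prediction of step velocity asymmetry and adapts the
    per-leg swing-initiation thresholds by gradient descent on the
    sensory prediction error. A reduced-order event-driven walker closes
    the loop at desk scale, and an analysis layer provides step length and
    velocity asymmetry series, spatial-temporal decomposition (center of
    oscillation, limb phasing), exponential adaptation-curve fitting, and
    waveform similarity measures. Includes a tiered treadmill objective
    function and a CMA-ES driver for controller parameter optimization.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
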