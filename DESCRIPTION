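Package: untether
Title: Rotational-Resistance Effects on Motor-Cortex Activity in Tethered Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying how tether rotational resistance
    affects motor-cortex neural activity in behaving mice. Provides synthetic
    generators for GCaMP6m-like calcium (delta-F/F) traces, open-arena
    trajectories and head-fixed platter rotations; open-field kinematics
    (walking distance, turning angle, angular speed) and velocity-threshold
    locomotion segmentation; detection of calcium firing events and the
    per-event fluorescence-rate statistic r = deltaS/deltaT; per-neuron
    nonparametric (Mann-Whitney U) comparison and classification across
    experimental conditions with consistent-trend identification; and a
    discrete-time closed-loop simulator of a proactive torque-compensating
    optoelectrical commutator (torsional-spring tether, threshold-triggered
    microstepping).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
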