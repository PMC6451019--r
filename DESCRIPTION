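Package: sensillum
Title: Passive Electric-Circuit Modeling of Ephaptic Coupling Between
    Olfactory Receptor Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Steady-state electric-circuit model of an insect olfactory
    sensillum housing two olfactory receptor neurons (ORNs) that share a
    common transepithelial potential. Provides morphometry-based somatic and
    dendritic resistances, Hill-type odorant activation of the dendritic
    conductance, calibration of somatic batteries to a common resting
    potential, closed-form and direct Kirchhoff solutions of the circuit,
    forward simulations of dose-response curves and ephaptic inhibition
    (background activation, mixture sublinearity, spike/LFP slope ratios),
    simultaneous multi-sensillum nonlinear least-squares fitting of local
    field potential dose-response data, and a seeded synthetic-data
    generator for parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
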