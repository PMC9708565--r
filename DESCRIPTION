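Package: foragerl
Title: Reinforcement Learning of Foraging Trajectories and Hippocampal
    Population Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates spatial (arena) and non-navigational (joystick) target
    foraging tasks together with a trajectory-generating reinforcement-learning
    agent that adapts speed gain and heading offset by a mean-shift-plus-
    homeostasis (MeSH) rule, including optogenetic-perturbation variants, a
    hazard-gated movement-initiation model and an epsilon-greedy gridworld
    baseline. Provides the companion analysis pipeline for behavior
    (trace preprocessing, attempt segmentation, prior-trial-conditioned
    learning deltas, peri-event bootstrap tests) and for calcium-imaging
    populations (synchronous population event detection and clustering,
    event-triggered principal-component loadings, occupancy-normalized place
    maps, response reliability, peri-movement sorting, consensus linear
    decoding via the Moore-Penrose pseudoinverse, and cross-day ROI matching),
    plus a synthetic-data generator with known ground truth used to validate
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    cluster,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
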