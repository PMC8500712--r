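Package: shoalbout
Title: Nearby-Interaction Bouts and Turning Bias from Fish Group Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trajectory-based quantification of social-like nearby
    interactions and repetitive turning bias in four-fish group recordings.
    Detects pairwise proximity bouts from tracked X-Y coordinates, corrects
    bout durations for the chance passing-by time expected from the group's
    swimming speed, calibrates distance and duration cutoffs against a
    random-regrouping null ensemble with Holm-corrected tests, computes
    kinematic metrics (inter-individual and nearest-neighbour distances,
    speeds, region occupancy, signed turning angles and a turning-bias
    index), and provides an agent-based four-fish simulator with tunable
    attraction and turn bias plus downstream statistics (AIC-selected
    generalized linear models, logarithmic-curve fits, intraclass
    correlation, paired and rank tests).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
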