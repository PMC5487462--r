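Package: passdyn
Title: Behavioral Dynamics of Pick-and-Place Movements and Pass Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates and analyses a tabletop pick-and-place task in which an
    agent moves objects from a pickup location to a target location and decides,
    trial by trial, whether to transport the object alone or pass it to a
    partner. Hand movements are generated by goal-directed heading dynamics (a
    damped angular spring steering the end-effector toward the goal) coupled to
    a second-order non-constant velocity law; the pass/no-pass decision is a
    bistable normal-form dynamical system driven by the body-scaled
    environment-to-agent (E/A) ratio of target distance to reach, exhibiting
    saddle-node bifurcations and hysteresis across ascending and descending
    target sweeps. Includes the full simulated-experiment protocol (trial
    grids, block schedules, noise injection, pass-location jitter), and an
    analysis suite for transition-point estimation, trajectory curvature and
    velocity profiling, occupancy heat maps, pass-location clustering, and
    radial distribution fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
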