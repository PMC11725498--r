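Package: tethersim
Title: Simulation and Analysis of Single-Tether Neural Acquisition and
    Freely Moving Behavior
Version: 0.1.0
Authors@R:
    person("Open", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A software model of a multi-device neural acquisition link and
    its behavioral consequences: heterogeneous device streams multiplexed
    over one serialized channel with a tunable block-transfer model,
    torque-free tether commutation driven by absolute head orientation,
    lighthouse-style sweep-timing triangulation fused with inertial
    orientation, a simulated-time closed-loop stimulation harness with
    latency accounting, and occupancy/heading entropy statistics with block
    bootstrap confidence intervals for freely moving behavior. Includes
    seeded device simulators and a synthetic trajectory generator so every
    component is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
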