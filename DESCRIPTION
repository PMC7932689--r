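Package: arslip
Title: Spring-Loaded Inverted Pendulum Models and Tripod Gait Analysis for
    Insect Walking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the mechanics and interleg coordination of
    hexapod walking. Implements the spring-loaded inverted pendulum (SLIP)
    and angular-radial SLIP (ARSLIP) point-mass models of centre-of-mass
    motion, the springy-tripod model and its quadratic reduction to ARSLIP,
    gait quantification from footfall timing and Hilbert leg phases,
    per-step kinematic descriptors, constrained multi-start fitting of the
    models to tracked centre-of-mass trajectories, prediction of effective
    spring constants from tripod geometry, classification of walking
    kinematics into fly-like and cockroach-like regimes, and a synthetic
    data generator emulating high-speed tracking of walking flies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    lhs,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
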