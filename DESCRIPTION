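Package: gaitphase
Title: Online Gait-Phase Detection for Walking with a Robotic Prosthesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Online detection of gait phases from wearable-sensor signals
    (instrumented-insole vertical ground reaction forces and centre of
    pressure, summed hip and knee joint angles, and sagittal foot angular
    velocity) sampled at 100 Hz. Implements a rule-based finite-state
    machine with threshold transition rules dividing a steady-state walking
    stride into four phases (left stance, left-right double stance, right
    stance, right-left double stance) plus quiet standing, initiation and
    termination states; an alternative supervised classifier using one
    three-state Gaussian hidden Markov model per walking phase with
    sliding-window likelihood arbitration; a seeded synthetic gait-signal
    simulator providing labelled ground truth; and evaluation utilities
    computing per-phase detection success ratios with sound and prosthetic
    side mapping.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: jsonlite, stats, tools, utils, yaml
Suggests: optparse, testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
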