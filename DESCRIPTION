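Package: speechsfc
Title: Hierarchical State-Feedback Control Simulation of Speech Motor Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates speech motor control as hierarchical state feedback
    control. A task-level dynamical controller drives timed constriction
    goals (gestural scores), an articulatory-level controller inverts the
    task-to-articulator kinematics through a weighted Jacobian
    pseudoinverse, and both act on an internal articulatory state estimate
    produced by an augmented-state Unscented Kalman Filter that fuses
    efference copy of motor commands with noisy auditory (formant) and
    somatosensory (position/velocity) feedback. The auditory forward model
    is learned from self-generated babbling data with a locally weighted
    projection-regression scheme. Includes a surrogate vocal-tract plant
    with a closed-form formant map, and batch experiment harnesses for
    feedback-deprivation, sensory-noise sweeps, mechanical jaw clamping,
    and auditory first-formant perturbation paradigms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    yaml,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
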