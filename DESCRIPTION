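Package: catchup
Title: Catch-Up Saccade Triggering During Smooth Pursuit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and analysis of catch-up saccade triggering during
    smooth pursuit of a double step-ramp target. Provides a stochastic trigger
    model (Kalman-filter estimation of position error and retinal slip,
    linear extrapolation to a predicted position error, confidence
    accumulation to a decision threshold), a double step-ramp task and
    session-schedule generator, a synthetic eye-trace generator with ground
    truth, the per-trial analysis chain (zero-phase low-pass filtering,
    central-difference kinematics, acceleration-threshold saccade detection,
    exclusion rules, predicted-error and crossing-time metrics), and
    repeated-measures group statistics with Bonferroni post-hocs and a
    BIC-approximated Bayes factor.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
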