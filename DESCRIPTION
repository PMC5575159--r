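Package: emgnarx
Title: Continuous Decoding of Arm Kinematics from Surface EMG with NARX
    Recurrent Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuous, simultaneous decoding of shoulder, elbow and wrist
    joint angles from six-channel surface electromyography (EMG). Implements
    the full myoelectric decoding pipeline: EMG linear-envelope extraction
    (rectification, causal low-pass Butterworth filtering, decimation to the
    decoding rate), a small NARX (nonlinear autoregressive with exogenous
    inputs) recurrent network trained by Levenberg-Marquardt with multiple
    restarts and closed-loop refinement, contiguous five-fold
    cross-validation scored by variance accounted for (VAF), a prediction
    interval sweep, and one-way repeated-measures ANOVA with Bonferroni
    pairwise comparisons. A synthetic arm-plant generator produces paired
    EMG/kinematics trials (minimum-jerk reaching, velocity-driven reciprocal
    muscle activations, amplitude-modulated band-limited EMG carriers) with
    known ground truth, so the whole pipeline is testable without recorded
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    tools,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    withr
Config/testthat/edition: 3
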