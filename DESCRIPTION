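Package: hillexo
Title: EMG-Driven Hill-Type Muscle Simulation and Adjoint-Based
    Calibration for a Single-Joint Exoskeleton
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differentiable musculoskeletal simulation of a single-joint
    (knee) exoskeleton driven by surface electromyography.  Implements the
    EMG-to-activation processing chain (band-pass filtering, envelope
    extraction, recursive neural-activation dynamics and a nonlinear
    activation shaping function), a Hill-type muscle-tendon model for the
    eight knee muscle-tendon units grouped into four EMG channels, the
    rigid-body motion equation of the exoskeleton with adaptive
    Runge-Kutta-Fehlberg integration, least-squares identification of the
    joint inertial parameters, and the continuous adjoint method for
    analytical gradients of per-muscle parameters (optimal fiber length,
    maximum isometric force, tendon slack length) with respect to a
    trajectory-matching loss.  Includes Adam/SGD fitting loops,
    Nelder-Mead and finite-difference baselines with exact
    loss-evaluation accounting, a PID assist-torque controller, and a
    synthetic-experiment generator so that the whole pipeline can be
    exercised without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    minpack.lm,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
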