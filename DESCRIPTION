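Package: semgforce
Title: Surface-EMG Driven Elbow Force Estimation and Mirror-Assist Simulation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for real-time estimation of isometric elbow-joint force from
    two-channel surface electromyography (biceps and triceps) and for simulating
    a mirror bilateral assist loop on a variable-stiffness elbow actuator. The
    package implements the full conditioning chain (DC removal, 50 Hz notch,
    fourth-order Butterworth band-pass, rectification, MVC normalization),
    sliding-window time-domain feature extraction (MAV, RMS, DASDV, WL), a small
    backpropagation neural network (8-3-1) force estimator with target
    anti-normalization, a PID force-tracking simulation of a series-elastic
    elbow joint, per-trial evaluation metrics (RMSE and squared correlation),
    and a seeded synthetic sEMG/force generator so the whole three-phase
    protocol (offline learning, online validation, real-time assist) runs
    without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
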