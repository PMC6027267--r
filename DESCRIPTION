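Package: eegreach
Title: Hierarchical EEG Decoding of Arm-Lifting and Hand-Reaching Intention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage pipeline for decoding upper-limb motion intention from
    multichannel scalp EEG and estimating distal-arm kinematics for prosthesis
    control. Stage one classifies arm lifting, hand reaching, or rest from
    movement-related cortical potential amplitudes, delta and alpha band power,
    and running RMS features, using single-hidden-layer neural networks or
    k-nearest-neighbour classifiers, and gates the prediction against residual
    limb motion. Stage two estimates elbow angle and hand endpoint from the
    decoded class and shoulder-angle history with networks trained
    leave-one-subject-out on a pooled motion database. Includes a synthetic
    session generator that emulates the assumed cue protocol, event-locked
    slow cortical potentials, alpha attenuation and shoulder-elbow-endpoint
    kinematic relationships, plus evaluation utilities (accuracy, chance
    level, exact binomial significance, table aggregation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    signal,
    stats,
    yaml
Suggests:
    jsonlite,
    nnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
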