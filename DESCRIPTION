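Package: coordrqa
Title: Attractor Stability of Movement Coordination Patterns via
    Recurrence Quantification Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the stability of rhythmic versus
    discrete motor coordination patterns from motion-capture marker
    trajectories. Implements the full analysis chain for metronome-paced
    juggling-like tasks: kinematic preprocessing (Butterworth filtering
    with residual-analysis cutoff selection, differentiation, cycle
    extraction and length standardization), a spectral Coordination
    Pattern Index measuring the concentration of vertical hand-velocity
    power at the fundamental movement frequency, time-delay embedding
    with average-mutual-information delay selection and false-nearest-
    neighbors dimension selection, recurrence quantification (%REC,
    %DET, %MAXLINE) with a compiled counting core, sensorimotor
    synchronization scoring (%Asynchrony) for ramped metronome trials,
    and correlation summaries with Fisher-z aggregation and Bonferroni
    correction. Includes a synthetic-kinematics generator spanning the
    rhythmic-to-discrete continuum so the whole pipeline can be
    exercised end to end without motion-capture data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
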