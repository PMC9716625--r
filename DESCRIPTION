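Package: duosync
Title: Audiovisual Coordination Features and Perceived Togetherness in Musical Duos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how continuously rated "togetherness" of duo
    music performances relates to objective coordination features of the
    performers. Computes quantity of motion and cross-wavelet (Morlet)
    coordination power from motion-capture marker trajectories, RMS sound
    intensity and note-onset asynchronies from audio and note-event data,
    converts sparse slider-rating logs to evenly sampled series, selects the
    perceptual response lag by participant-folded k-fold cross-validation of
    AR(1) linear mixed models, and fits the modality-by-expertise model
    battery together with ANOVAs, Tukey contrasts and body-part comparisons.
    A synthetic-data module generates complete duo studies (motion, onsets,
    intensity, ratings, eye-gaze fixations) with known ground truth so every
    stage of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    nlme,
    lme4,
    lmerTest,
    emmeans,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
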