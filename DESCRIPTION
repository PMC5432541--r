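Package: srpsearch
Title: Saccade-Related Potentials and Eye Features in Structured Visual Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A co-registered EEG and eye-tracking analysis pipeline for
    structured visual search tasks in which screen locations are highlighted
    sequentially and the observer must later report which locations held
    targets. Provides EOG-based saccade detection (despiking, blink removal,
    derivative-of-Gaussian velocity estimation, direction-matched saccade
    selection), saccade-locked EEG epoching with bad-channel handling and
    outlier rejection, fixation-duration and pupil-size feature extraction
    from gaze streams, group statistics (pointwise paired t-tests with
    Benjamini-Hochberg correction), and single-trial linear-SVM
    classification of target versus non-target and hit versus miss fixations.
    Includes a synthetic-data generator that emulates the task structure and
    the statistical signatures the analysis assumes, with ground-truth
    annotations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
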