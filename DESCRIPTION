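Package: avencode
Title: Inverted Encoding Analysis of Audiovisual Super-Additivity in EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing super-additive multisensory enhancement in
    multivariate neural responses. Implements an inverted encoding model that
    decodes stimulus location from multichannel stimulus-locked epochs,
    signal-detection (d') and accuracy readouts of the reconstructions,
    maximum-likelihood-estimation and aggregate (sensor-concatenation)
    additive baselines, mass-based cluster permutation statistics for
    timecourse comparisons, psychometric-function fitting for behavioural
    sessions, and a fully parameterised synthetic-data generator (session
    schedules, ideal-observer responses, gaze traces, and tuned multichannel
    epochs with a controllable non-linear audiovisual interaction) so that
    every stage of the pipeline has a parameter-recovery test surface.
    Also includes the binaural (interaural time and level difference)
    rendering model used to position auditory stimuli on a display.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    readr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
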