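Package: ocuload
Title: Ocular Cognitive-Load Estimation from Gaze and Pupil Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to estimate operator cognitive load from wearable
    eye-tracker recordings. Implements velocity-threshold (I-VT)
    fixation/saccade classification, saccadic-intrusion detection, a
    spectral pupillometric workload index (sum of 1-5 Hz FFT magnitude
    bins of the pupil-diameter signal over short buffers), pilot
    inceptor-workload metrics (duty cycle, aggressiveness) and tracking
    error for a sum-of-sines boundary-avoidance task, phase-wise event
    rates, and the associated statistical comparisons (one-way ANOVA with
    eta-squared, pairwise and Welch t-tests, correlations). A synthetic
    gaze/pupil/tracking/flight generator with exported ground truth
    supports validation of every pipeline stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
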