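Package: gazebias
Title: Saccadic Orienting Toward Images: Time-Course, Mixture and Exploration Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for saccadic orienting toward images: saccade
    event detection from raw gaze samples, endpoint recoding and trial
    filtering, Gaussian-kernel smoothed endpoint-versus-latency time courses
    with cluster-based permutation inference, unimodal versus bimodal
    endpoint-distribution model comparison via scaled-Gaussian fits and BIC
    information weights, and gaze-exploration analyses (distance-to-center
    time courses, saccade rate, spatial heatmaps, endpoint-variability
    ANOVAs). A synthetic gaze-data generator provides ground truth for every
    pipeline stage so the full analysis is verifiable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    car,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
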