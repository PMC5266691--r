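Package: emospect
Title: Spectral EEG Correlates of Ten Positive Emotions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline linking subjective ratings of ten positive
    emotions to EEG spectral power in a film-clip viewing paradigm.
    Provides a synthetic-data generator with planted ground truth
    (three-cluster rating structure and a channel-by-band-by-item effect
    map), baseline-corrected band-power feature extraction, rating
    reliability and similarity analysis with non-metric multidimensional
    scaling, correlation topographies, and median-split cross-validated
    classification of 1-s epoch features, per participant and at the
    grand-average level.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    MASS,
    signal,
    e1071,
    data.table,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'design.R'
    'signal-features.R'
    'classification.R'
    'io.R'
    'generate-ratings.R'
    'ratings-analysis.R'
    'neural-correlation.R'
    'generate-eeg.R'
    'pipeline.R'
    'cli.R'
    'emospect-package.R'
    'utils.R'
RoxygenNote: 7.3.3
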