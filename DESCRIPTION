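Package: beatassr
Title: Steady-State EEG Responses to the Beat of Music
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the cortical auditory steady-state response
    (ASSR) at the beat frequency of melodic stimuli. Provides tools to encode,
    scramble and synthesize single-line melodies while preserving their
    envelope spectrum; to extract amplitude and phase of the beat-frequency
    response from multi-channel EEG, including selection of beat-responsive
    channels against neighboring spectral bins; a three-level statistical
    ladder (trial, subject, population) for condition differences in response
    amplitude; linear discriminant classification of paired-difference
    features with greedy forward channel selection and repeated stratified
    cross-validation; and a synthetic-EEG generator with known ground truth
    for end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
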