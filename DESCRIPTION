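Package: odortrace
Title: Population Analysis of Odor and Post-Odor Calcium Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing multi-trial calcium-imaging recordings of
    odor-evoked population activity: ROI extraction from image stacks,
    delta-F/F preprocessing with exponential photobleaching correction,
    threshold-based categorization of response dynamics (on, off,
    prolonged), time-resolved population-vector Pearson correlation with
    significance masking and animal-level bootstrap envelopes, and
    sliding-window nu-SVM decoding of odorant identity with a
    permutation-derived chance band.  A synthetic-data generator emulates
    odor-specific population dynamics with ground-truth labels so every
    stage of the pipeline can be validated without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    minpack.lm,
    jsonlite,
    yaml,
    data.table,
    tiff,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
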