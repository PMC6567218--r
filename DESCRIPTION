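Package: uareeg
Title: Unsupervised Artefact Removal for Multichannel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised detection and removal of ocular and muscular
    artefacts in multichannel EEG recordings. Potential artefact portions are
    detected from autoregressive AR(2) features of sliding windows via the
    distance of each interval to the feature centroid; a local window around
    each artefact is decomposed with FastICA; ordered independent-component
    projections are subtracted per electrode until a two-sample
    variance-equality test against an artefact-free reference stops the
    process. Includes a seeded synthetic contaminated-EEG generator, MSE and
    detection-score evaluation utilities, EDF/BDF/CSV input-output, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
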