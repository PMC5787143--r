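Package: emgdecomp
Title: Intramuscular EMG Decomposition into Motor Unit Action Potential Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes single-channel intramuscular electromyography (EMG)
    recordings into their constituent motor unit action potential (MUAP)
    trains through six stages: wavelet de-noising, active-segment detection by
    resting-epoch recognition, peak alignment with Daubechies wavelet-domain
    feature extraction, minimum-spanning-tree single-linkage clustering with
    refinement, supervised minimum-distance classification with template
    adaptation, and pseudo-correlation peel-off resolution of superimposed
    waveforms. Includes a synthetic EMG generator with known templates and
    renewal firing patterns, the DR/AR/CCR performance indices for evaluation
    against ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
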