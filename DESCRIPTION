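Package: painlfp
Title: Bilateral Anterior Cingulate LFP Analysis of Mechanical Pain Intensity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for bilateral local field potential (LFP)
    recordings from the anterior cingulate cortex during mechanical
    nociceptive stimulation: zero-phase Butterworth/notch preprocessing with
    iterative Grubbs trial rejection and session z-scoring, evoked-potential
    P1/N1/P2 parametrization, Morlet-wavelet scalograms with baseline
    z-normalization and five-band interval statistics, pain-intensity
    decoding with band-limited mean-absolute-value features, minimum-
    redundancy maximum-relevance feature selection and a Gaussian-kernel
    support vector machine, and interhemispheric connectivity via
    phase-locking value, sliding-window Pearson correlation and
    cross-correlation lag estimation. Includes a seedable synthetic
    bilateral-LFP trial generator with ground truth so every stage is
    testable as a recovery problem.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    pROC,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
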