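Package: fcreliab
Title: Test-Retest Reliability of Functional Connectomes Across Scan Durations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how reliable individual functional connectomes
    are as a function of post-censored scan duration. Starting from parcellated
    BOLD time series and head-motion traces, the package filters motion
    parameters, computes framewise displacement, censors high-motion volumes,
    builds Fisher-z Pearson connectomes, and estimates test-retest correlation
    (FC-TRC) curves by split-session and iterative subsampling approaches,
    together with ICC(2,1) reliability at edge, network, and parcel level,
    motion-group classification from post-censored volume counts, functional
    network template matching with group-consensus maps, signal-quality
    statistics, and behavioral engagement scores. A synthetic multi-session
    cohort generator with known ground-truth connectomes and a controllable
    two-state motion model provides a parameter-recovery test surface for
    every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
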