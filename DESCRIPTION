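Package: restdyn
Title: Resting-State EEG Dynamics: Multiscale Entropy, Spectral Power and
    Task Partial Least Squares
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing resting-state electroencephalography in
    repeated-measures group designs. Implements multiscale sample entropy
    (coarse-graining plus sample entropy with an Rcpp core), normalized
    single-trial spectral power density with canonical band summaries, and
    mean-centered task partial least squares with permutation tests and
    bootstrap-ratio stability maps. A seeded synthetic-EEG generator with
    controllable 1/f slope, band-limited oscillations and artifact
    injection reproduces the statistical structure of a two-group,
    pre/post training study so that every stage of the pipeline can be
    exercised and calibrated without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
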