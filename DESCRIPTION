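Package: flimreach
Title: FLIM-FRET Lifetime Fitting and Disordered-Linker Reach Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for time-correlated single-photon-counting (TCSPC)
    fluorescence-lifetime imaging (FLIM) analysis: a periodic two-component
    reconvolution decay model with sub-bin instrument-response-function
    drift correction, Poisson maximum-likelihood and weighted-least-squares
    fitting, lifetime-based FRET efficiency estimation, group statistics
    (Welch t-tests, one-way ANOVA with simulation-based Dunnett comparisons
    to a control), closed-form and Monte-Carlo polymer models (ideal chain,
    worm-like chain) of disordered-peptide end-to-end reach, and a
    synthetic-data generator that produces complete in-silico FLIM
    experiments with known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    multcomp,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
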