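Package: cysPTM
Title: Sequence-Based Prediction of Cysteine S-Sulfenylation Sites
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for predicting S-sulfenylation (and, generically, any
    cysteine-centered post-translational modification) sites from protein
    sequence. Provides sequence-window fragment extraction with terminal
    padding, exact-duplicate homology reduction between training and testing
    sets, eight fragment encodings (one-hot binary, amino-acid and
    amino-acid-pair composition, BLOSUM62, position weight matrix, PSI-BLAST
    position-specific scoring matrix, solvent accessibility and secondary
    structure tracks, AAindex physicochemical indices), F-score driven forward
    selection of physicochemical properties on top of a base feature, a
    radial-basis-function support vector machine trained by sequential minimal
    optimization with stratified k-fold cross-validation, and two-sample-logo
    style position-specific residue enrichment statistics. A synthetic data
    generator emulates the compositional and solvent-accessibility structure
    of S-sulfenylation neighbourhoods so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    methods,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    quadprog
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
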