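Package: ssvepAlign
Title: Within-Subject Transfer Learning for SSVEP Brain-Computer Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Decoding and within-subject transfer-learning toolkit for
    steady-state visual evoked potential (SSVEP) brain-computer interfaces.
    Implements the standard canonical correlation analysis (CCA) decoder and
    its filter-bank variant, template-based extended CCA (eCCA), transferred
    template CCA (ttCCA), task-related component analysis (TRCA), and an
    align-and-pool domain-adaptation decoder (ALPHA) that bridges cross-day
    and cross-electrode (wet/dry) domain shifts by orthogonal-Procrustes
    alignment of spatial patterns and CORAL covariance alignment. Includes a
    seeded synthetic SSVEP generator with planted domain shifts, transfer
    evaluation protocols (cross-validation, transfer-direction enumeration,
    information transfer rate, training-block curves, topography and
    covariance similarity analyses), and a lightweight epoch container with a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'ssvepAlign-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'stimulus.R'
    'simulate.R'
    'filters.R'
    'signalproc.R'
    'cca.R'
    'templates.R'
    'trca.R'
    'alpha.R'
    'score-engine.R'
    'decode.R'
    'evaluation.R'
    'study.R'
    'io.R'
    'cli.R'
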