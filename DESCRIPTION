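Package: flexMUSIC
Title: Flexible-Extent Recursive MUSIC Source Localization for M/EEG
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Subspace methods for the M/EEG inverse problem that recover both
    the location and the spatial extent of neural sources. Implements
    FLEX-MUSIC, a recursive MUSIC variant that scans a dictionary of
    graph-smoothed leadfields so that candidate sources range from single
    dipoles to cortical patches of increasing radius, together with the
    RAP- and TRAP-MUSIC baselines, automatic signal-subspace selection,
    and a weighted minimum-norm reconstruction of the source time courses.
    Includes a simulation engine for single-dipole and extended patch
    sources with 1/f temporal spectra and channel-correlated sensor noise
    at controlled SNR, evaluation metrics (mean localization error, earth
    mover's distance, mean squared error, sparsity), and a reproducible
    benchmark runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'benchmark.R'
    'flexMUSIC-package.R'
    'io.R'
    'metrics.R'
    'run.R'
    'simulation.R'
    'solvers.R'
    'source-space.R'
    'subspace.R'
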