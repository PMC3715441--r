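Package: sirspread
Title: Stochastic and Mean-Field Models of Multi-Mark Epigenetic
    Silencing in Budding Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a minimal five-state nucleosome-modification model
    of Sir-mediated telomeric silencing in Saccharomyces cerevisiae.
    Nucleosomes carry one of five mutually exclusive marks (Sir-bound,
    unmodified, H4K16-acetylated, H3K79-methylated, or doubly marked and
    transcriptionally active) and interconvert through basal and
    cooperative enzymatic reactions with exponentially weighted
    neighborhood coupling. The package provides the well-mixed
    (mean-field) phase analysis (fixed points, stability, phase
    classification, bistability scans), an event-driven Gillespie lattice
    simulator with a finite titrated pool of Sir proteins, silencing-front
    tracking with zero-velocity-line estimation, and steady-state
    observables: density profiles, bound-Sir fraction, spatial power
    spectra, and the correlation length of the silenced mark from a
    Lorentzian spectral fit.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
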