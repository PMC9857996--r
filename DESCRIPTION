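Package: specbind
Title: Spectroscopic Analysis of Protein-Ligand Binding, FRET Distances,
    and Iron-Release Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for characterizing protein-polyphenol
    interactions by steady-state fluorescence spectroscopy: a
    ligand-depletion (quadratic mass-action) quenching isotherm with
    multi-start nonlinear fitting of stoichiometry and per-site binding
    constant, a Forster resonance energy transfer (FRET) spectroscopic
    ruler (spectral overlap integral, Forster radius, transfer efficiency
    and donor-acceptor distance with validity checks), emission peak-shift
    quantification, and ferrozine-based iron-release kinetics (Beer-Lambert
    conversion, cubic progress-curve fits with initial rates,
    percent-inhibition, and FeSO4 calibration equivalence). Includes seeded
    synthetic-data generators emulating every input so the full pipeline is
    testable without instrument data, and a report runner chaining the
    stages into one JSON summary.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    pracma,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
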