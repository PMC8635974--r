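Package: ligandbias
Title: Quantification of GPCR Ligand Bias from Resonance-Energy-Transfer Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis chain for quantifying agonist bias at a
    G protein-coupled receptor from FRET and BRET recordings: spectral
    correction and baseline correction of single-cell ratio traces,
    per-application amplitude extraction and within-cell normalization,
    plate-reader BRET phase analysis, one- and two-phase exponential decay
    fitting, Hill and competition-binding curve fitting with Cheng-Prusoff
    conversion, constrained global fitting of the Black-Leff operational
    model of agonism with shared slope and fixed affinities, log(tau/Ki)
    transduction coefficients relative to a reference agonist, and
    cross-pathway rank-order comparison with tie groups. Includes a
    synthetic-data generator with known ground truth so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
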