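Package: amparkin
Title: Kinetic, Fluctuation, FRAP and Interface-Stability Analysis of AMPA
    Receptor Gating
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing pH modulation of AMPA-type glutamate
    receptor gating and of the N-terminal-domain (NTD) dimer-of-dimers
    interface.  Includes a Markov-chain channel simulator (deterministic
    master-equation and exact stochastic ensembles), exponential decay and
    rise fitting with amplitude-weighted time constants, paired-pulse
    recovery-from-desensitization extraction with Hodgkin-Huxley-type
    fitting, Hill dose-response fitting, nonstationary fluctuation analysis
    (variance-mean parabola), FRAP double normalization and
    single-exponential recovery fitting, Henderson-Hasselbalch protonation
    assignment, molecular-dynamics trajectory interface metrics (r.m.s.d.
    traces, contact-distance evolution, pairwise-distance s.d., residue
    encounter times, rupture-onset detection), and static-structure
    measurements (center-of-mass and terminus distances, interface
    residues, two-fold tetramer construction).  Seeded synthetic-data
    generators provide currents, FRAP traces and rupture trajectories so
    every analysis stage is testable without experimental recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    bio3d,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
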