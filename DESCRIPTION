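Package: spinedyn
Title: Biochemical Signalling and AMPA-Receptor Plasticity in the Dendritic Spine
Version: 0.2.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic mass-action simulation of the post-synaptic
    signalling network of a cortical dendritic spine, covering the CaMKII,
    PKA, and PKC pathways and their control of GluR1/GluR2 AMPA-receptor
    subunit phosphorylation and trafficking. Includes a statistical
    AMPA-receptor tetramer model mapping membrane-bound subunit pools to
    total maximal synaptic conductance, the standard LTP/LTD induction
    protocols (HFS, 4xHFS, LFS, theta-burst trains, square pulses, bath
    application, spike-timing pairings driven by imported or synthetic
    calcium flux traces), parameter-manipulation presets (pathway blockades,
    phosphorylation-site-deficient receptors), plasticity-curve
    classification, single-parameter robustness scans, and multi-objective
    (NSGA-II) fitting of protein-concentration scalers to cortical LTP/LTD
    measurements.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    Matrix,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
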