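Package: qestr
Type: Package
Title: Rigid-Rotor Harmonic-Oscillator Partition Functions and
    Machine-Learned Estimators for Gas-Phase Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Computes gas-phase molecular partition functions in the
    rigid-rotor/harmonic-oscillator approximation from geometries and
    harmonic vibrational frequencies, including automatic detection of the
    external rotational symmetry number, and assembles transition-state
    theory rate constants.  Provides dataset construction with temperature
    sampling uniform in inverse temperature, Bemis-Murcko scaffold
    hold-out and fold splitting, EncodedBond-style 3D featurization, and
    feed-forward neural-network estimators (Qest, QesTS and their Double
    composition) that predict transition-state partition functions without
    a transition-state geometry search.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    nnet,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
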