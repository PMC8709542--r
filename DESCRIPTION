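Package: fhnec
Title: Frequency- and Time-Domain Analysis of the FitzHugh-Nagumo Neuron
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying neuronal excitability in the FitzHugh-Nagumo
    (FHN) membrane model with dimensional electrical parameters. Computes the
    stationary current-voltage curve, nullclines and fixed points; performs
    linear stability analysis (trace/determinant classification, Hopf,
    saddle-node and pitchfork bifurcation location); maps the linearized model
    onto its small-signal equivalent circuit (membrane capacitor, kinetic
    inductor, negative differential resistance) and generates complex
    impedance spectra with automatic classification into spectral regimes;
    and integrates the full nonlinear equations to obtain spike trains, limit
    cycles, damped ring-downs and bistable jumps. The frequency-domain and
    time-domain pictures are cross-validated through the Nyquist stability
    criterion: the zeros of the impedance are the eigenvalues of the Jacobian.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
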