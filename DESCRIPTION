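Package: caflux
Title: Calcium Transient Kinetics and Fluorescence Trace Analysis for
    Mechanically Stimulated Epithelial Cells
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing mechanically evoked cytosolic calcium
    transients in epithelial monolayers. Implements a deterministic
    single-cell model of relative cytosolic Ca2+ and Na+ concentrations
    with leak, pump, calcium-induced calcium release (CICR) and a
    Na+-inhibited Na+/Ca2+ exchanger (NCX); a fluorescence-trace feature
    pipeline (baseline normalisation, amplitude, 50% decay time,
    target/neighbor/other cell classification, amplitude-quantile group
    averaging); least-squares fitting of the model to averaged traces with
    shared kinetics and per-group stimulus influx; in-silico perturbations
    (mechanosensitive-influx sweep, store depletion, sodium-free medium);
    photostimulation arithmetic (diffraction-limited beam width, energy
    dose, shear speed); and a synthetic trace/layout generator for testing
    the whole pipeline without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    tools,
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
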