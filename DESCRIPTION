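Package: optospike
Title: Simulation and Analysis of All-Optical Electrophysiology Screens in
    Spiking HEK Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Conductance-based simulator of optogenetically excitable
    "spiking HEK" cells (NaV + Kir2.1 + a channelrhodopsin actuator and a
    fluorescent voltage-indicator readout) together with the complete
    trace-analysis and screening statistics used in all-optical sodium
    channel pharmacology: blue-light stimulus protocols, photobleach
    correction, spike extraction, the use-dependence index and
    spike-amplitude dispersion, recovery-from-inactivation kinetics,
    Hill dose-response and Kv4.3 kinetic fits, Z-prime assay quality and
    5-SD hit calling on synthetic 384-well plates. State-dependent
    (use-dependent) drug block of the sodium conductance is modelled with
    a guarded-receptor scheme, so tonic blockers, slow-unbinding
    use-dependent blockers, fast-unbinding "alternans" blockers and
    inactivation-curve shifters can all be emulated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
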