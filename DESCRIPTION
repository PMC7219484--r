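Package: picostat
Title: Virtual Miniaturized Potentiostat for Voltammetric Method Development
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A software model of a coin-sized LMP91000/SAMD21 potentiostat and
    of the electrochemical cells it measures. Models the dual-stage voltage
    reference (a microcontroller DAC feeding the analog front end's 14-point
    bias ladder) and its quantization of requested cell potentials, generates
    the excitation waveforms for cyclic, square wave and normal pulse
    voltammetry and chronoamperometry, emulates the transimpedance readout
    with internal-zero subtraction, feedback RC low-pass filtering and
    additive white/line noise, and simulates synthetic cells (a diffusing
    Nernstian redox couple and a surface-adsorbed reversible species with a
    target-induced signal gain) so the whole chain runs without hardware.
    Includes a voltammogram analyst: least-squares baseline tangent, peak
    current relative to the tangent, noise statistics with a 3-sigma limit of
    detection, and instrument-comparison metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
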