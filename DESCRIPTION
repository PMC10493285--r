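Package: ifatsim
Title: Event-Driven Emulation of a Conductance-Based Integrate-and-Fire
    Array Transceiver
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale software emulator of an integrate-and-fire array
    transceiver (IFAT): two-compartment conductance-based leaky
    integrate-and-fire neurons with four first-order synapses per neuron,
    pulse-width-and-amplitude (PWAM) coded synaptic strength spanning more
    than three decades of conductance step, address-event representation
    (AER) codecs with virtual wiring through external routing tables, a
    two-tier micro-pipeline timing and throughput model, per-neuron analog
    mismatch generation with single-point digital offset calibration, a
    rectified-linear mean-rate approximation of the neural transfer
    function, and vision demonstrations (orientation tuning curves and
    boundary detection with Gabor kernels).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
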