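Package: mearf
Title: MEA Spike-Train Analysis and Thermometric RF Dosimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-electrode array (MEA) recordings of
    cortical neuronal cultures under radiofrequency (RF) or thermal exposure
    protocols. Implements peak-to-peak threshold spike detection on raw
    multichannel waveforms, adaptive logISI burst detection, network-burst
    detection with an electrode-synchrony criterion, four per-phase network
    metrics (mean firing rate, mean bursting rate, mean burst duration, mean
    outside-burst firing rate) with baseline normalization, nonparametric
    phase statistics (Kruskal-Wallis omnibus with Conover all-pairs
    post-hoc), and thermometric estimation of the specific absorption rate
    (SAR) from the initial slope of temperature transients. A synthetic-data
    generator emulates bursting cultures with phase-restricted suppression
    and first-order heating curves so the whole pipeline is testable without
    laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
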