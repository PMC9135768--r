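Package: tadgaze
Title: Spino-Ocular and Vestibulo-Ocular Motor Integration in Larval Amphibians
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based simulation of a bilateral spinal central
    pattern generator coupled to vestibulo-ocular and efference-copy
    pathways driving extraocular motoneurons, together with the
    accompanying motor time-series toolkit: spike-train integration and
    burst metrics, Morlet wavelet spectrograms and periodograms with
    surrogate-based significance, swim-cycle kinematics (gain, phase,
    eye-position eccentricity and magnitude modulation), circular phase
    statistics, and seeded generators of synthetic eye, tail and nerve
    traces for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
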