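Package: b0gate
Title: B0-Map Based Eligibility Screening for MR-Guided Radiotherapy
    near Cardiac Implants
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulates implant- and lead-perturbed off-resonance (B0)
    fields on a moving phantom, acquires wrapped dual-echo phase maps
    under cos^4 respiratory and cardiac motion, removes phase wraps with a
    quality-guided region-growing algorithm, quantifies static-vs-dynamic
    agreement (Bland-Altman limits of agreement, distance shells around
    signal voids), converts off-resonance into geometric distortion via
    the readout bandwidth, and emits a wrap-presence based eligibility
    verdict for MR-guided radiotherapy of targets near cardiac
    implantable electronic devices. A companion module reproduces MR
    gradient-induced ECG artifacts and their effect on automatic
    heart-rate detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    Rcpp,
    RNifti,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
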