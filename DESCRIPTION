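Package: stafkit
Title: Spatio-Temporal Action Fields from M-Sequence Reverse Correlation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: System identification of parallel visual figure-tracking
    subsystems from maximal-length shift-register (m-sequence) stimulation.
    Generates m-sequences and compound figure/texture stimulus protocols,
    simulates a quasi-linear two-stream behavioral plant (elementary-motion
    and figure-motion channels), estimates the two temporal kernels per
    figure azimuth by sign-flip decoupled circular cross-correlation with
    dc-error correction, assembles them into spatio-temporal action fields
    (STAFs), forward-predicts steering responses to arbitrary figure
    trajectories, and compares STAF populations with pixelwise paired
    t maps under Benjamini-Hochberg false discovery rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
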