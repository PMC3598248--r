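Package: afmech
Title: AFM Force-Curve Analysis and Cellular Stiffness Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Processes atomic force microscopy (AFM) approach curves from
    soft biological samples: baseline detrending, contact-point detection,
    conversion to indentation-force data, and Young's modulus estimation
    with the Sneddon model for conical/pyramidal tips. Implements the
    per-cell and per-group averaging scheme used in developmental
    cochlear-mechanics studies, along with companion quantification
    operators (microtubule density, cell aspect ratio, line-scan
    fluorescence intensity, gel-lane relative densitometry, delta-delta-Ct
    fold change) and the Student and Welch two-sample comparisons.
    Includes synthetic-data generators with ground-truth manifests for
    parameter-recovery validation of the full pipeline.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
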