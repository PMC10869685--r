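Package: dvscreen
Title: Dual-View Mammography Screening with Detector Ensembling and Triage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Breast-cancer screening support from paired cranio-caudal (CC)
    and mediolateral-oblique (MLO) mammographic views. Implements a
    breast-wise abnormality classifier built from two feature extractors, a
    learnable linear block that maps MLO features toward CC feature space,
    and a combined cross-entropy plus cosine-alignment training loss; a
    pluggable object-detector contract with per-class non-maximum
    suppression and multi-model ensembling; an OR-threshold decision rule
    that fuses classifier probability with suspicious-mass objectness into a
    four-tier radiologist priority queue; grouped k-fold cross-validation by
    study; and a deterministic synthetic mammogram generator with ground
    truth boxes so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    EBImage,
    pROC,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
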