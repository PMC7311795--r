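Package: sonomark
Title: Interpreting and Suppressing Burned-In Caliper-Marker Shortcuts in
    Ultrasound Nodule Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying and mitigating the adversarial effect of
    burned-in clinician caliper markers on ultrasound nodule detection and
    classification. Provides a seeded speckle-phantom generator with
    ground-truth nodules, a clinical caliper-marker model (tangency placement,
    pseudo-marker groups, random marker mixup), exemplar-based
    texture-synthesis inpainting with an optional learned coarse
    reconstruction model, a variational-information-bottleneck (VIB) crop
    classifier with a matched cross-entropy baseline, a sliding-window patch
    detector with non-maximum suppression, interpolated average-precision
    evaluation at configurable IoU thresholds, and an experiment runner that
    reproduces the marker-shortcut phenomenon across marker-layered,
    marker-removed and marker-mixed training conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
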