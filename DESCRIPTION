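Package: thzwheat
Title: Terahertz Spectroscopic Wheat-Quality Recognition by Multi-Source Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recognising storage-induced wheat quality defects
    (normal, germinated, moldy, worm-eaten) from terahertz time-domain
    spectroscopy. Simulates class-conditional time-domain traces through a
    physical slab forward model, extracts absorption-coefficient and
    refractive-index spectra from reference/sample trace pairs, builds PCA
    feature sets per optical modality, trains kernel support-vector-machine
    sub-classifiers, and fuses them either at the feature layer
    (concatenation plus a single SVM) or at the decision layer
    (Dempster-Shafer evidence combination with an epsilon-threshold decision
    rule). Includes confusion-matrix reporting with per-class and overall
    recognition rates and a model-comparison report.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
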