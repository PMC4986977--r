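Package: erpdecode
Title: Decoding the Locus of Covert Visuospatial Attention from Lateralized ERPs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and decoding pipeline for covert visuospatial
    attention experiments with a modified Posner cueing task. Generates
    multi-subject synthetic EEG with lateralized event-related potential
    (ERP) components (N2pc/SPCN-like contralateral negativities and
    target-locked contralateral positivities), preprocesses it with the
    standard ERP chain (Butterworth band-pass filtering, mastoid
    re-referencing, epoching, baseline correction, peak-to-peak ocular
    artifact rejection), extracts twelve lateralized ERP amplitude
    features per subject and cued location, and decodes the attended
    location with a dendrogram multi-class support vector machine (a
    binary SVM at each node of a hierarchical-clustering-derived decision
    tree). Evaluation includes leave-one-subject-out cross-validation,
    row-normalized confusion matrices, a mean letter-position distance
    statistic with visual-angle conversion, exact binomial significance
    thresholds, and permutation testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
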