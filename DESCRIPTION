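Package: nbscreen
Title: Machine-Learning Triage for Tandem Mass Spectrometry Newborn Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification tools for newborn screening panels measured by
    tandem mass spectrometry. Implements per-disease cutoff triage into
    negative, suspected and positive cases; signed primary weights from class
    median differences; manifested features (products and ratios of top-ranked
    analytes); two-class F-score feature ranking; exhaustive feature-subset
    search with a radial-basis-function support vector classifier under a
    100%-sensitivity criterion; stratified 5-fold cross-validated model
    selection; and two-stage prediction (cutoff gate then classifier) with
    confusion-matrix and sensitivity/specificity/accuracy reporting. Includes
    a seeded synthetic cohort generator emulating rare metabolic disease cases
    (phenylketonuria, hypermethioninemia, 3-MCC deficiency) so the whole
    pipeline is testable without access to screening-centre data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
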