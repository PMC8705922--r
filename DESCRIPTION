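Package: stillwatch
Title: Contactless Immobility Detection in Visible and Thermal Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects human immobility (a surrogate for potential
    unconsciousness in remote triage) from short visible-light or thermal
    video clips. The pipeline preprocesses a reference frame with a person
    mask, its morphological skeleton and a white grid, selects Shi-Tomasi
    feature points inside the body region, tracks them with pyramidal
    Lucas-Kanade optical flow, thresholds per-instant displacement
    magnitudes into a movement-count signal, and classifies the clip as
    moving or nonmoving. Includes an articulated-silhouette scene
    simulator that emulates the experimental protocol (postures, body
    angles, seven movement classes, visible/thermal rendering, nuisance
    effects), and an imbalanced-classification metric suite (F-beta,
    Cohen's kappa, Matthews correlation, balanced error rate,
    precision-recall AUC) with study-level reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
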