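Package: rugometry
Title: Landmark-Based Morphometric Comparison of Palatal Rugae Across
    Imaging Modalities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative rugoscopy toolkit for forensic odontology.
    Implements a six-point palatal-rugae landmarking protocol (five
    parallel reference lines through the upper incisors intersected with
    the first two rugae), least-squares similarity superimposition of
    landmark configurations, six geometric descriptor families (absolute
    and maximum-normalised inter-landmark distances, landmark-polygon
    perimeter, area and compactness shape factor, and Hu invariant
    moments computed by exact polygon integration), Pearson
    correlation/determination matching with interpretive bands, cohort
    summary tables with Wilcoxon-Mann-Whitney method comparison and a
    paired-design sample-size calculator, plus a seeded synthetic
    palate/modality generator (clinical photograph, plaster cast,
    intraoral scan) so the whole agreement study runs offline with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
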