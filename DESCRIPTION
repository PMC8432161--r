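Package: lesionplan
Title: Surface-Based Cortical Lesion Detection and sEEG Implantation Planning
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Automated detection of focal cortical dysplasia candidates from
    per-vertex cortical surface features and integration of the detected
    clusters with stereoelectroencephalography (sEEG) implantation planning.
    Provides readers and writers for FreeSurfer binary surfaces, curv and MGH
    overlays, Slicer FCSV fiducials and cohort tables; per-vertex feature
    preprocessing (geodesic Gaussian smoothing, within- and between-subject
    z-scoring, interhemispheric asymmetry on a symmetric template); a
    one-hidden-layer neural-network vertex classifier with PCA-determined
    hidden size, Youden-index thresholding and leave-one-out
    cross-validation; surface cluster extraction with area filtering;
    cluster-to-electrode-contact colocalization; extra-electrode planning
    rules; Monte-Carlo cohort power calculation; and a fully synthetic cohort
    generator so the whole pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
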