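Package: stromaquant
Title: Quantitative Analysis of Corneal Stromal Ultrastructure, Mechanics
    and Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying an ex vivo corneal ectasia model:
    segmentation of collagen fibril cross-sections in transmission electron
    micrographs with adaptive thresholding, stereological fibril density
    estimation by randomly placed counting windows (median estimator),
    fibril diameter distributions, reduction of uniaxial tensile records to
    Young's modulus, detection of collagen denaturation temperatures in
    differential scanning calorimetry thermograms, delta-delta-Ct relative
    gene expression, and group-comparison statistics. A synthetic-data
    module generates every input with known ground truth (hard-core disk
    packings rendered as micrograph-like rasters, J-shaped stress-strain
    records, endotherm thermograms, and qPCR Ct tables) so each estimator
    can be validated by parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
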