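Package: aomontage
Title: Fast Feature-Based Montaging of Adaptive-Optics Retinal Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stitches multimodal adaptive-optics scanning light ophthalmoscope
    (AOSLO) image tiles into retinal montages. Detects multi-scale FAST corners
    ranked by a Harris measure, attaches intensity-centroid orientations, and
    computes rotated 256-bit binary (BRIEF-style) descriptors. Descriptors are
    matched by Hamming distance through locality-sensitive hashing with a ratio
    test, tile pairs are aligned by single-correspondence RANSAC translation
    estimation, and montages are grown greedily from random tiles of reference
    with a good-enough acceptance rule and nominal-position pruning. Includes
    overlap-based quality metrics (normalised cross correlation, normalised
    mutual information), an overlap-requirement sweep harness, and a synthetic
    photoreceptor-mosaic fixture generator for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    tiff,
    png,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
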