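Package: spheromorph
Title: Automated Morphometry and Growth Quantification of Tumor Spheroids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated image analysis of brightfield/H&E micrographs of
    multicellular tumor spheroids (MCTS). Unmixes hematoxylin and eosin
    stains by optical-density color deconvolution, segments spheroids with
    the histogram-minimum auto-threshold, filters particles by a minimum
    pixel area, and measures size, roundness (moment-ellipse shape
    descriptor) and solidity (hole-filled versus unfilled mask area ratio).
    Downstream utilities aggregate replicate measurements (mean, SD, n) and
    quantify treatment response as percent size variation relative to a
    baseline day. A synthetic H&E image generator renders ground-truth
    annotated spheroid fixtures so every pipeline stage is verifiable
    without experimental micrographs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    tiff,
    jpeg,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
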