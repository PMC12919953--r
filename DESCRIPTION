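Package: punctapolar
Title: Planar Cell Polarity Quantification from Fluorescent Puncta
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies planar cell polarity from single-channel fluorescence
    images of punctate protein signal and matching cell label masks (Cellpose
    convention). Puncta are detected by log transformation, percentile
    normalization and thresholding, labeled as connected components, size
    filtered and assigned to cells; each cell's polarity vector is the
    size- or intensity-weighted mean of unit vectors from the cell centroid
    to its puncta centroids, expressed relative to a reference direction
    (a fixed tissue axis or a target point such as a wound). Angular
    distributions are binned into rose-plot histograms and tested for
    uniformity with the chi-square test. A synthetic-epithelium generator
    (Voronoi cells, von Mises-biased Gaussian puncta) provides ground truth
    so the whole pipeline is verifiable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
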