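Package: coarseshape
Title: Coarse-Grained Cell Shape Measurement in Confluent Tissues with
    Compact Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures locally averaged cell shape (long axis, short axis,
    orientation of the window-averaged inertia ellipse) in images of
    confluent tissues with small convolutional neural networks, without
    per-cell segmentation at analysis time. Provides ground-truth
    construction from label images via second central moments, a
    doubled-angle sine/cosine encoding of orientation, a compact CNN
    engine (convolution, max pooling, dropout, Adam, early stopping)
    written in C++, cross-validated grid search and Hyperband
    architecture optimization, a decision-tree meta-analysis of
    architecture hyperparameters, a seeded synthetic Voronoi-tissue
    generator for end-to-end testing, and assembly of coarse-grained
    anisotropy maps over large images from overlapping tiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    rpart,
    stats,
    utils,
    tiff,
    png,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
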