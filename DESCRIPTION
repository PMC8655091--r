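Package: epistratify
Title: Reference-Based Deconvolution of Breast Epithelial Cell Subtypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-based cell-type deconvolution for bulk DNA methylation
    and RNA-seq data, centred on the RLM-pseudo-inverse estimator: per-sample
    robust (Huber) linear regression against a cell-type signature matrix,
    followed by adaptive noise thresholding and sum-to-one normalisation, with
    an optional hierarchical two-stage procedure for estimating breast
    epithelial subtype proportions (luminal progenitor, luminal mature, basal)
    within a general cell-type decomposition. Includes signature-matrix
    construction from labelled single-cell data by a modified Mahalanobis
    ranking or a negative-binomial differential-expression ranking, selection
    of discriminative DNA methylation loci from purified profiles, GMM-LE
    clustering (Gaussian mixture models fitted in a regularised graph-Laplacian
    eigenspace) for labelling single cells, quantile-matching augmentation of
    bulk reference profiles onto single-cell library distributions, standard
    methylation and single-cell preprocessing filters, and a noise-corruption
    robustness simulation with parameter-recovery reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    Matrix,
    mclust,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
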