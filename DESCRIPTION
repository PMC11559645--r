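Package: dyadSTORM
Title: Cluster and Colocalization Analysis of Dyad Proteins in SMLM Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for single-molecule localization microscopy
    (STORM/SMLM) data of cardiac dyad proteins. Detects ryanodine-receptor
    (RyR2) clusters by DBSCAN with cluster-morphology constraints (span and
    localization-count limits), quantifies partner-channel (junctophilin-2 or
    CaV1.2) colocalization within a fixed search radius around each cluster
    centroid, computes nearest-neighbor distances between cluster centroids,
    size-binned histograms, and ROI/cell/animal/group summary statistics with
    one-way ANOVA and Tukey HSD group comparisons. Includes a synthetic
    two-channel SMLM scene generator with planted dyad-row geometry, full
    ground truth, and euthyroid/hypothyroid/T3-treated condition presets for
    validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
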