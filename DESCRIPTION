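Package: venation
Title: Leaf Venation Network Phenotyping from Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to turn calibrated, segmented leaf images into quantitative
    venation phenotypes. A binary vein mask is skeletonized with a
    topology-preserving thinning, converted to an undirected vein graph by
    endpoint/branch-point pixel rules with adjacent-node merging and
    deterministic edge tracing, and summarized by a 28-dimensional egonet-based
    (NetSimile-style) network feature vector. Downstream helpers provide
    stratified cross-validated random-forest species classification, a PCA
    morphospace, homography-based frame rectification with square-marker area
    calibration, an overlap-tile segmentation harness with a pluggable
    segmenter, and a seeded synthetic venation generator that supplies
    ground-truthed planar-graph rasterizations for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    deldir,
    igraph,
    EBImage,
    png,
    tiff,
    tools,
    randomForest,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'venation-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'synthetic.R'
    'skeleton.R'
    'features.R'
    'segmentation.R'
    'calibration.R'
    'morphospace.R'
    'io.R'
    'pipeline.R'
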