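Package: toothseg
Title: Global-Local Attention Segmentation of Intraoral-Scan Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semantic segmentation of dental arches from intraoral-scanner
    surface data. Converts triangular meshes to point clouds, subsamples
    centers by farthest point sampling, groups k nearest neighbours and
    encodes each neighbourhood by relative coordinates and distances, then
    classifies every point into gingiva or one of 32 FDI tooth classes with
    a network that fuses max-pooled local features with a multi-head
    self-attention global branch aggregated by attention pooling and soft
    pooling. Includes a full training loop (Adam, augmentation, early
    stopping), confusion-matrix metrics (OA, mAcc, mIoU, mDice, per-tooth-type
    tables), a synthetic labelled dental-arch generator covering normal,
    crowded, missing-tooth, malformation and partial-eruption scenarios, and
    a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
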