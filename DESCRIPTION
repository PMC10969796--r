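Package: replikit
Title: Single-Cell Analysis of Genome Replication Progression in 3D
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative single-cell tools for comparing genome replication
    progression between pluripotent and somatic human cells from multichannel
    3D fluorescence microscopy and genome-wide origin maps. Provides 3D
    nucleus and replication-foci segmentation (seeded region growing with
    Gaussian-fit stopping thresholds and marker-based watershed splitting),
    repli-FISH replication timing by binary-mask AND colocalization,
    ratiometric EdU/PCNA fork-speed proxies, hidden Markov random field
    chromatin compaction classification with intensity-weighted signal
    mapping, replication-origin clustering and inter-origin distance
    statistics, cell-cycle gating from DAPI/EdU intensities, and a synthetic
    image and interval generator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    tiff,
    EBImage,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    minpack.lm,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
biocViews: CellBiology, Microscopy, Segmentation, SingleCell
RoxygenNote: 7.3.3
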