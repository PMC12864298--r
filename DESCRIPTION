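Package: dryshift
Title: Semi-Supervised SAR-Optical Fusion Mapping of Tropical Dry Forest Change
Version: 0.1.0
Authors@R: person("dryshift", "maintainers", email = "maintainers@dryshift.dev", role = c("aut", "cre"))
Description: A desk-scale pipeline for land-use/land-cover (LULC) mapping and
    change detection in fragmented tropical dry forest landscapes from paired
    optical (fine resolution) and SAR backscatter (coarse resolution) rasters.
    Provides a synthetic paired-scene generator with gamma speckle and injected
    class transitions; raster preparation (temporal median compositing,
    NDVI/GNDVI indices, global min-max normalization, patch chunking,
    tile-grouped splits, resampling); a dual-encoder Y-Net convolutional
    segmentation network trained with a soft Jaccard loss, AdamW and a
    one-cycle learning-rate schedule; k-means-ensemble pseudo-labeling for
    semi-supervised training; ensemble post-classification change detection
    with hectare accounting and error margins; and Getis-Ord Gi* hot/cold-spot
    statistics on change rasters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
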