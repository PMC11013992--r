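Package: dfseg
Title: Dynamic Fusion Segmentation of Orchard Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semantic segmentation of LiDAR point clouds from orchard and
    nursery scenes with a dynamic fusion segmentation network. Provides the
    XYZL/PLY point-cloud I/O and preprocessing used in tree phenotyping
    pipelines, a training-free local feature aggregation encoder built from
    trigonometric positional embeddings and a farthest-point-sampling /
    k-nearest-neighbour set-abstraction hierarchy, fusion segmentation
    modules that pair two layers' per-point class scores in a C-by-C
    multi-embedding space, a self-contained training and prediction engine
    (per-point cross-entropy plus an auxiliary pairing loss, AdamW), point-wise
    accuracy and mean-intersection-over-union evaluation, and a parametric
    generator of labelled synthetic orchard scenes for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
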