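Package: annotiler
Title: On-the-Fly Tiling of Whole-Slide Polygon Annotations into Masks and Back
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Serves (image tile, annotation mask) pairs directly from a store of
    class-labelled polygon annotations in slide coordinates, without pre-tiling
    to disk. Annotations in the QuPath GeoJSON dialect are indexed with a packed
    STR R-tree, queried and clipped per tile, and discretized to single-label or
    per-class masks under an explicit, subpixel-aware pixel-selection rule
    (cell-center sampling, with a top-left corner-sampling baseline for
    comparison). Prediction masks are vectorized back into slide-coordinate
    polygons, and same-class polygons are merged across tile borders.
    Discretization quality is scored with subpixel intersection-over-union by
    exact polygon clipping and with boundary Hausdorff distance; a synthetic
    star-polygon dataset and toy-shape fixtures make every step testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr,
    yaml
Config/testthat/edition: 3
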