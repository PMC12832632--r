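Package: regenhubnet
Title: Spatiotemporal Co-Expression Networks and Hub-Gene Mapping for
    Regenerating Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted gene co-expression networks per cell-type and
    per condition from annotated single-cell spatial transcriptomics,
    following the metacell-based (hdWGCNA-style) workflow: KNN metacell
    aggregation, soft-threshold selection by scale-free topology fit,
    topological overlap, deterministic module detection, module eigengenes
    and kME-based hub ranking. Downstream tools derive condition-specific
    (regeneration-restricted) gene sets by set algebra over module
    membership, summarize exported protein-protein interaction edge tables,
    and quantify spatial co-localization of a marker gene with an annotated
    cell population both on cell coordinates and on raster images
    (RGB thresholding, binary dilation, composite rendering). A synthetic
    data generator with planted module structure and an injury-induced
    marker time course makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    png,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
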