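Package: mplexqc
Title: Quality Control for Single-Cell Data from Highly Multiplexed Tissue Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and redacts single cells affected by microscopy artifacts
    in highly multiplexed tissue images (cyclic immunofluorescence, CODEX and
    related assays). Provides an automated morphology/flood-fill artifact
    detector, file-driven region-of-interest gating, Gaussian-mixture nuclear
    intensity and segmentation-area gates, cross-cycle DNA-ratio filtering for
    cell loss, per-channel percentile outlier pruning, a clustering-based audit
    of the redaction (metaQC), and post-QC phenotyping tools (Horn's parallel
    analysis, UMAP/t-SNE embedding, HDBSCAN clustering, silhouette scoring,
    cluster expression profiles with agglomerative meta-clusters, per-condition
    cluster frequency statistics and thumbnail galleries). A synthetic tissue
    phantom generator with per-class ground truth supports validation of every
    stage, and a structured redaction log makes each run replayable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    mclust,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    uwot,
    withr,
    yaml
Suggests:
    mgcv,
    optparse,
    Rtsne,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
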