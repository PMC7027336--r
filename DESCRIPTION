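Package: tracer3d
Title: Serial-Section 3D Reconstruction and Tracer-Spread Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs serial-section fluorescence image stacks into
    volumetric datasets and quantifies intraparenchymal tracer spread.
    Provides rigid intensity-based stack registration, brightness
    equalization, anisotropic volume assembly with maximum projections,
    Otsu binarization of the tracer channel, hemisphere-split positive-voxel
    counts, an exact anisotropic Euclidean distance transform for the
    nearest-positive-voxel spread statistic, lymph-node tracer quantification
    with autofluorescence channel subtraction, vessel-versus-parenchyma
    normalized intensity comparison, and the accompanying nonparametric
    statistics (Kruskal-Wallis with Dunn-Bonferroni post hoc, Wilcoxon
    signed rank, Mann-Whitney U, paired t). A synthetic-phantom generator
    with full ground truth supports end-to-end testing without raw slide
    scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    png,
    yaml,
    jsonlite,
    nortest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
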