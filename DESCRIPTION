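Package: neurogeom
Title: Geometric Analysis of Neurite Morphology from 3D Grayscale Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for nanometer-scale morphometry of neuronal processes in
    three-dimensional grayscale image volumes. Provides synthetic tubular
    phantom generation with closed-form differential geometry, TIFF volume
    input/output, centerline tracing driven by 3D Sobel gradients and
    gradient vector flow, a fixed-column PDB-dialect interchange format for
    node-chain structural models, discrete Frenet curvature and torsion
    estimation (Menger curvature, signed binormal torsion), and the
    cohort-level statistical battery used in comparative neurite morphometry
    (Welch's ANOVA, two-way ANOVA, Bartlett, Kolmogorov-Smirnov with
    Holm-Bonferroni correction, and structure-relationship regressions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
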