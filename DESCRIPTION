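Package: volnet
Title: Structural Covariance Brain Networks from Regional Volumes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <maintainer@example.org>
Description: Builds group-level structural covariance networks from tables of
    regional brain volumes and assesses their small-world topology. Provides
    atlas-based regional volume estimation from template label maps and
    Jacobian-determinant fields, partial-correlation edge estimation with
    Ledoit-Wolf covariance shrinkage, sparsity-thresholded binarization,
    graph metrics (clustering coefficient, characteristic path length,
    global and local efficiency) with degree-preserving rewired null models,
    and repeatability and group-comparison statistics (intraclass correlation,
    Bland-Altman limits of agreement, per-region ANOVA, permutation tests on
    network metrics). Includes a synthetic cohort generator that emulates
    skull-stripping workflow biases for end-to-end validation, and a
    one-command pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    RNifti,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
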