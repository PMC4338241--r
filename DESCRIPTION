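Package: cranioreg
Title: Evaluation of 3D Superimposition Techniques for Serial Craniofacial Surface Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and evaluation pipeline for rigid superimposition of
    serial three-dimensional craniofacial surface models. Generates seeded
    synthetic skull phantoms (paired pre- and post-treatment CT-like volumes
    with ground-truth rigid transforms, landmarks and a reference-region
    atlas), extracts triangle meshes by isosurfacing, registers them with
    three-point landmark registration or region-masked robust iterative
    closest point (point-to-plane), and quantifies accuracy and precision of
    five reference-structure choices. Includes a statistics layer with
    permutational MANOVA for balanced crossed mixed designs, permutation
    tests of multivariate dispersion, pairwise permutation t-tests with
    Bonferroni correction, and Bland-Altman agreement summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
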