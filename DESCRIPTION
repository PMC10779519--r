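Package: zcmesh
Title: Zernike-Canterakis Moments and Shape Retrieval for Triangular
    Surface Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact, volume-like computation of geometric and
    Zernike-Canterakis (ZC) moments of closed triangular surface meshes by
    the Pozo-Koehl tetrahedral decomposition, with rotation-invariant 3D
    Zernike descriptors in the sense of Novotni and Klein. Includes a
    protein structure retrieval pipeline: PDB cleaning and selection,
    biological assembly reconstruction, PCA confidence-ellipsoid outlier
    residue elimination, geometric features (smoothed effective-atom
    distance histograms, per-axis size, mesh volume), a family of
    ZC-descriptor shape distances with similarity tiers, and ROC
    benchmarking of superfamily retrieval.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
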