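Package: craniomod
Title: Landmark-Based Analysis of Cranial Modularity and Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for landmark-based geometric morphometric analysis of
    phenotypic modularity in 3D cranial data. Reads and writes multi-specimen
    landmark datasets (TPS, NTS, CSV), imputes missing landmarks by thin-plate
    spline interpolation, performs Generalized Procrustes Analysis and static
    allometry correction, estimates Euclidean Distance Matrix Analysis (EDMA)
    mean forms and landmark covariances for exploratory trait clustering (Ward
    linkage, Gap statistic, bootstrap Jaccard stability), and evaluates a
    priori modular architectures by maximum likelihood over congruence
    coefficient correlation matrices (AICc model selection) and by the
    covariance ratio statistic with permutation tests and effect sizes. A
    synthetic landmark-data generator with known modular covariance provides a
    ground-truth test bed for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    cluster,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    Matrix
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
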