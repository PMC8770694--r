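Package: craniomorph
Title: Geometric Morphometrics and Phylogenetic Comparative Analysis of
    Cranial Landmark Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for three-dimensional geometric morphometric analysis of
    cranial landmark configurations in a phylogenetic comparative framework,
    motivated by the question of how extrinsic (diet, habitat, productivity)
    and intrinsic (size allometry, modularity, phylogenetic inertia) factors
    shape cranial diversity in bovids.  Provides landmark file input/output
    (TPS and long-format CSV), generalized Procrustes analysis, thin-plate
    spline estimation of missing landmarks, principal component and
    phylomorphospace ordination, permutation linear models with residual
    randomization (ordinary and phylogenetic generalized least squares),
    multivariate phylogenetic signal, disparity and evolutionary-rate
    comparisons, modularity assessment (covariance ratio, likelihood-based
    model comparison, gap-statistic module discovery), ecological covariate
    construction from gridded occurrence tables, and a seeded synthetic-data
    generator emulating the structure of a multi-specimen cranial dataset on
    a dated phylogeny.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phytools,
    cluster,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
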