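Package: ConnectomeStats
Title: Weighted Structural Connectome Construction, Graph Measures, and
    Disease-Effect Inference
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds subject-level weighted structural brain networks from
    deterministic-tractography streamline tallies, mean fractional anisotropy
    and regional volumes over a 92-node parcellation (90 AAL regions plus
    bilateral substantia innominata); computes local (degree, strength,
    Onnela clustering, nodal path length, betweenness centrality) and global
    (mean degree/strength, clustering, characteristic path length, global
    efficiency) graph measures; normalizes global measures against ensembles
    of Maslov-Sneppen degree-preserving random graphs to obtain gamma, lambda,
    normalized global efficiency and small-worldness; and fits
    covariate-adjusted general linear models for independent and interaction
    effects of Alzheimer's disease-related and Lewy body-related cognitive
    impairment on network measures and cognition, with AIC-guided model
    selection and Benjamini-Hochberg false-discovery-rate control. A synthetic
    cohort generator emulating the study design (group sizes 37/22/19/36,
    six covariates, 14 standardized cognitive scores, plantable network
    effects) makes the full pipeline testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Network, GraphAndNetwork, StatisticalMethod, Regression
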