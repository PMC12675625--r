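Package: glymphdti
Title: Diffusion MRI Microstructure, Glymphatic (DTI-ALPS) and Phenotype
    Clustering Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for multi-shell diffusion MRI
    studies of early neurodegeneration. Generates ground-truth digital
    phantoms and synthetic clinical cohorts, forward-simulates multi-shell
    diffusion-weighted signals under a three-compartment neurite model with
    Watson orientation dispersion, fits diffusion tensors (FA) and NODDI
    parameters (ICVF, ODI, ISO), computes the DTI-ALPS perivascular-flow
    index, builds white- and gray-matter skeletons with metric projection
    (TBSS/GBSS analogues), performs permutation inference with
    threshold-free cluster enhancement and covariate adjustment, derives
    gait asymmetry and dual-task-cost metrics, and partitions patients by
    k-medoids on Gower distances with silhouette-based model selection and
    bootstrap stability validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    pracma,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
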