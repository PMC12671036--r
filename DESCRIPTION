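Package: psdstack
Title: Comparing Clinical, Lesion and Connectome Models of Post-Stroke Depression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for comparing predictive models of post-stroke
    depressive symptoms (CES-D at three months) built from complementary tiers
    of information: clinical covariates, macroscopic radiological lesion
    location, atlas-based lesion loads, parcel-wise structural disconnectomes
    derived from a normative streamline connectome, and weighted graph-topology
    metrics of the spared network. Provides a synthetic cohort generator with
    planted, recoverable effects; exact streamline-lesion intersection
    disconnectomes; a 15-metric topology feature vector; GLM and (non-negative)
    LASSO tiers with repeated stratified cross-validation; AIC-based model
    comparison with relative probabilities; a network-based statistics (NBS)
    permutation test; and forward deviance-criterion hierarchical stacking of
    model predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    glmnet,
    igraph,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    readr,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
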