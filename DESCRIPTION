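Package: bandpop
Title: Population Genetics of Dominant Marker Band Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for dominant molecular markers (ISSR, RAPD,
    AFLP) scored as binary band-presence matrices. Computes per-primer
    marker-efficiency indices (PIC, EMR, MI, resolving power,
    discriminating power), POPGENE-style diversity statistics (Na, Ne,
    Nei's gene diversity, Shannon's index, Ht, Hs, Gst, Nm), Nei genetic
    identity and distance with UPGMA and Ward clustering, covariance PCA
    of band profiles, and a Bayesian admixture model for dominant diploid
    data (Gibbs sampler with correlated allele frequencies), including
    Evanno delta-K model selection and per-cluster fixation indices. A
    synthetic band-matrix generator with Balding-Nichols differentiated
    cluster frequencies provides ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
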