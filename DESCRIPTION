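Package: CloneScape
Title: Clonality, Diversity, Demography and Seascape Connectivity for
    Partially Clonal Populations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for population-genomic analysis of partially clonal
    organisms such as brown seaweeds. Detects clones (multilocus
    genotypes) from pairwise genetic distances with an automatic
    distance-cutoff predictor, and summarises per-site evolvability with
    clonal richness R, the inbreeding coefficient F_IS and the
    standardised index of association r_bar_d with a permutation null.
    Provides individual-level structure analyses (PCA, non-negative
    matrix factorisation ancestry coefficients, neighbour-joining trees
    with locus bootstrap), two-population demographic inference on the
    folded joint site frequency spectrum over a registry of 22
    divergence scenarios (SI/IM/AM/SC families with growth,
    linked-selection and heterogeneous-migration variants) using a
    structured-coalescent engine and composite Poisson likelihood,
    multi-generation stepping-stone seascape connectivity, and
    morphometric analyses (undulation index, trait PCA, dendrogram
    congruence). A synthetic-data module generates genotype matrices,
    dispersal matrices and trait tables with known truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    ape,
    igraph,
    vcfR,
    phangorn,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pheatmap
Config/testthat/edition: 3
RoxygenNote: 7.3.3
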