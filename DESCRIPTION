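Package: MicrobiomeSuccession
Title: Longitudinal Community-State Succession and Assembly Analysis for
    Host-Associated Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for longitudinal gut-microbiome succession analysis
    in peripartum cohorts: Dirichlet-multinomial mixture (DMM) community-state
    clustering with Laplace-evidence model selection, Markov-chain succession
    staging of community states, phylogenetic-bin null-model partitioning of
    community assembly processes (beta-NTI and modified Raup-Crick),
    compartment coupling via Procrustes superposition and Gibbs-sampler
    microbial source tracking, covariate fitting on ordinations, and
    species-pathway-phenotype mediation analysis. Includes a synthetic-cohort
    generator that emulates the longitudinal study design (latent Markov state
    paths, Dirichlet-multinomial count emission, phylogenetically conserved
    habitat preference, and planted mediation paths) so every stage can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    vegan,
    ape,
    randomForest,
    pROC,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr,
    picante,
    biomformat,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
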