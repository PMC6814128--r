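Package: provblup
Title: Pedigree-Based Genetic Evaluation of Provenance/Progeny Trials with
    Contemporary Genetic Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Animal-model BLUP and REML variance-component estimation for
    open-pollinated provenance/progeny trials, with four alternative treatments
    of population structure: provenance as a fixed effect, provenance as a
    random effect (for Qst estimation), and two contemporary genetic-group
    pedigree schemes including a phantom paternal pollen group for
    wind-pollinated species with long-distance pollen flow.  Provides sparse
    mixed-model equations with group-augmented pedigree A-inverses, univariate
    and bivariate (within-site and cross-site) REML, normal-score
    transformation of ordinal traits, a penalised quasi-likelihood fit for
    binary traits, heritability, Qst, breeding-value accuracy and
    genetic-correlation estimators with Taylor-series standard errors, Mantel
    and modularity comparisons of genetic-correlation matrices, and a
    synthetic trial generator for verifying every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    igraph,
    vegan
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
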