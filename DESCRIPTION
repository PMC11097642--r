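Package: viromeEco
Title: Community Ecology and Compositional Analysis of Viral-Family Count Matrices
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the statistical analysis of viromes summarized as
    sample-by-viral-family read-count matrices, as produced by read-based
    taxonomic classification of metatranscriptomes. Provides a
    SummarizedExperiment-derived container with host-domain and sample
    (species, phylum, habitat) annotations; run-metadata eligibility
    filtering and balanced one-run-per-species sampling; alpha-diversity
    (family richness, Shannon H') with ANOVA/AIC model selection, Levene
    checks, Box-Cox transforms and Tukey compact letter displays;
    compositional data analysis (relative abundance filtering, count-zero
    multiplicative imputation, centered log-ratio transform, Aitchison
    distances); distance-based PERMANOVA and PERMDISP with permutation
    p-values and pseudo-AIC model comparison; a bootstrap-balanced pairwise
    PERMANOVA/PERMDISP equivalence-network procedure; quantitative bipartite
    virus-host network structure (linkage density, H2', NODF nestedness,
    Barber modularity, d' specialization) with Patefield r2d null-model
    z-tests; and a Dirichlet-multinomial synthetic-data generator with
    ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    car,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Metagenomics, Microbiome, Virome, CompositionalData, Software
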