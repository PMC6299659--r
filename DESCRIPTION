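Package: diallelGS
Title: Genomic Selection Analysis for Partial-Diallel Conifer Progeny Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of genomic selection in control-pollinated
    forest progeny trials laid out as a partial diallel over two sites. Provides
    a synthetic trial generator (diallel pedigree, gene-dropped SNP genotypes,
    per-site additive effects with controllable genotype-by-environment
    correlation), VCF genotype quality control, pedigree (A) and genomic (G)
    relationship matrices, REML variance components and BLUP breeding values
    for single-site and joint-site animal models, narrow-sense heritability and
    type-B genetic correlation with a one-tailed boundary likelihood-ratio
    test, Bayesian whole-genome marker regressions (Bayesian ridge regression
    and Bayesian LASSO Gibbs samplers), Gaussian-kernel RKHS prediction, and a
    declarative cross-validation engine covering training/validation ratios,
    family and within-family subsampling, relatedness-structured splits,
    cross-site prediction, and marker-subset selection, with accuracy,
    predictive ability and relative-efficiency summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    vcfR
LinkingTo: Rcpp
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
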