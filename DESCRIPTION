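Package: cojoscore
Title: Conditional/Joint Analysis of GWAS Summary Statistics and Genetic
    Risk Score Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects allelic heterogeneity at GWAS loci by approximate
    conditional and joint (C/J) estimation of SNP effects from meta-analysis
    summary statistics combined with linkage-disequilibrium correlations
    from a reference genotype panel, using iterative stepwise model
    selection within regions around lead SNPs.  Builds weighted genetic
    risk scores from lead-SNP or joint effect estimates and quantifies
    their predictive value in an independent case-control cohort via AUC
    with the DeLong paired test, Nagelkerke's R-squared, AIC, and
    liability-scale variance explained under a disease-prevalence model.
    Includes a simulation module that generates LD-structured genotype
    panels, liability-threshold case/control phenotypes, and marginal
    logistic summary statistics with known ground truth, including presets
    for risk alleles masked by negative linkage disequilibrium.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
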