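Package: abokit
Title: Genomic Determination of ABO Blood Types with GWAS, Classification and Mendelian Randomization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for the genetics of the ABO
    blood-group system. Simulates cohorts with ABO functional alleles, tag
    SNPs at controlled linkage disequilibrium, serological phenotypes and
    quality-control contaminants; performs sample call-rate filtering,
    identity-by-descent relatedness pruning and principal-component
    analysis; runs per-SNP binomial and multinomial logistic association
    scans with covariate adjustment; selects independent hit SNPs by
    iterative linkage-disequilibrium screening including common-tag
    replacement; fits and evaluates multinomial genotype-to-blood-type
    classifiers (prevalence-threshold binary metrics, ROC/AUC, micro and
    macro F1); and estimates causal effects by one-sample and two-sample
    Mendelian randomization with inverse-variance-weighted and
    weighted-median estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    nnet,
    pROC,
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
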