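Package: rbgkit
Title: Recall-by-Genotype Study Design and Polygenic Score Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing recall-by-genotype (RbG)
    studies built on polygenic risk scores. Covers sample- and variant-level
    genotype quality control (call rate, Hardy-Weinberg exact test, minor
    allele frequency, heterozygosity outliers, relatedness), construction of
    a clumped, region-masked polygenic risk score from GWAS summary
    statistics, extreme-tail recall selection, Monte-Carlo and analytic
    power analysis for extreme-phenotype sampling designs, small-cohort
    group-comparison statistics (covariate-adjusted Cohen's d with
    noncentral-t confidence intervals, FDR control, lobe-level pooling of
    regional brain measures), and an inverse-variance-weighted
    summary-statistic association estimator. A synthetic-data module
    generates genotypes with block linkage disequilibrium, GWAS summary
    statistics, liability phenotypes and recall cohorts so the whole
    pipeline is exercisable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
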