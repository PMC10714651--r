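# rbgkit

Tools for designing and analysing **recall-by-genotype (RbG)** studies
built on polygenic risk scores (PRS), for statistical geneticists and
neuroimaging/cognition researchers who want to phenotype a small number
of genetically extreme individuals instead of a large unselected sample.

An RbG study genotypes a large population once, scores everyone with a
PRS (a weighted sum of risk-allele dosages, weights from GWAS summary
statistics), and recalls only individuals from the extreme tails of the
standardized score. Because the recalled sample is enriched for score
variance, a deeply phenotyped study of ~16 people can match the power of
an opportunistic sample of ~90.

The package covers the full chain:

* **Synthetic data** (`sim_genotypes`, `sim_gwas`, `sim_recall_cohort`,
  `sim_outcome_gwas`): genotypes in Hardy-Weinberg equilibrium with
  block-diagonal AR(1) linkage disequilibrium via a Gaussian copula,
  GWAS summary statistics with a planted causal fraction, and a
  10-low/6-high recall cohort with calibrated group effect sizes.
* **Genotype QC** (`qc_pipeline` and individual filters): call rates
  (< 95%), Hardy-Weinberg exact test (p < 1e-6, full enumeration),
  MAF (< 1%), heterozygosity outliers (inbreeding coefficient beyond
  3 SD), greedy relatedness exclusion (pi-hat > 0.2).
* **PRS construction** (`harmonize`, `clump`, `exclude_regions`,
  `compute_prs`, `select_recall`): allele harmonization, greedy LD
  clumping (1000 kb / r² 0.2 / P ≤ 0.5), APOE and MHC region masks,
  scoring with mean-imputed or omitted missing dosages,
  standardization, decile binning, and strict extreme-tail selection.
* **Design power analysis** (`design_spec`, `estimate_power`,
  `analytic_power_corr`, `effective_n`, `or_to_d`,
  `two_sample_t_power`, `decile_or`): Monte-Carlo power under the
  liability model *z = b·y + x* (default *b* = √0.095), extreme vs
  threshold vs random selection, Fisher-z analytic curves, effective
  sample size, and effect-size conversions.
* **Cohort statistics** (`compare_groups`, `summary_t_test`,
  `chisq_test`, `cohens_d`, `d_confint`, `bh_fdr`, `association`,
  `pool_regions`): covariate-adjusted Cohen's d with noncentral-t
  confidence intervals, family-wise BH-FDR, descriptive-table tests
  from printed summaries, and lobe-level pooling of atlas regions.
* **Summary-statistic replication** (`ivw`, `harmonize_pair`,
  `sumstats_qc_filter`, `prune`, `ivw_analysis`): the gtx-style
  inverse-variance-weighted PRS-association estimator
  β̂ = Σ bₓbᵧ/sᵧ² / Σ bₓ²/sᵧ², with its QC and pruning pipeline.

File formats: PLINK-1 bed/bim/fam (read/write), plain dosage TSV,
summary-statistic TSV (`CHR BP SNP A1 A2 BETA SE P FRQ INFO`), cohort
and kinship TSVs. A thin CLI over the same functions lives at
`inst/cli/rbg.R` (`simulate`, `qc`, `prs`, `power`, `ivw` subcommands).

## Worked example

```r
library(rbgkit)

# power of the 10/6 extreme-tail design vs an opportunistic sample of 16
estimate_power(design_spec(selection = extreme_selection(10, 6),
                           reps = 1000, seed = 7))
#> power = 0.940 (MC SE 0.0075, 1000 replicates)
estimate_power(design_spec(selection = random_selection(16),
                           reps = 1000, seed = 8))
#> power = 0.199 (MC SE 0.0126, 1000 replicates)

# closed-form power of the implied two-group contrast
two_sample_t_power(1.875, 10, 6)
#> [1] 0.921

# a synthetic recall cohort and its group comparison
co <- sim_recall_cohort(seed = 9)
compare_groups(co)[c(1, 3, 10, 11),
                   c("outcome", "d", "ci_lo", "ci_hi", "p", "p_fdr")]
#>                outcome      d  ci_lo  ci_hi      p p_fdr
#> 1            sam_total -1.045 -2.120 0.0667 0.0405 0.203
#> 3         sam_semantic -0.894 -1.949 0.1948 0.1189 0.297
#> 10 cingulate_thickness -0.656 -1.690 0.4052 0.1594 0.956
#> 11  hippocampal_volume  0.390 -0.644 1.4059 0.4816 0.977
```

The first two numbers say the extreme design rejects the null in 94% of
simulated studies where a random sample of the same size rejects in 20%
— the entire value of the design. The cohort table shows one simulated
cohort's covariate-adjusted standardized group differences (high-PRS
minus low-PRS) with noncentral-t 95% intervals and within-family FDR:
with n = 16 the intervals are wide, and single cohorts scatter around
the planted effects (−1.66, −1.99, −1.55, 0); the tests verify the
planted values are recovered in expectation across thousands of cohorts.

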