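# snpcc — case-control SNP association analysis with FPRP

`snpcc` implements the complete statistical pipeline of a candidate-SNP
case-control association study, the kind run to replicate GWAS hits in an
independent population: Hardy–Weinberg equilibrium (HWE) testing in
controls, odds ratios under the standard genetic models, combined
risk-genotype profiling, stratified subgroup analysis with heterogeneity
and interaction testing, and false-positive report probability (FPRP) with
power calculation. A reproducible cohort simulator (marginal and causal
modes) lets every stage be exercised and calibrated without access to
subject-level data.

It ships, as its canonical worked example, the printed genotype count
tables of a hospital-based stomach-cancer study in a Han Chinese
population (692 cases, 774 controls, frequency matched on age and sex)
covering four GWAS-identified SNPs: *PSCA* rs2294008 C>T and rs2976392
G>A, *PLCE1* rs2274223 A>G, and *MUC1* rs4072037 T>C.

## The statistics

For a 2×2 exposure–disease table with cells *a* (exposed cases), *b*,
*c*, *d*:

- **Odds ratio**: OR = *ad/bc*, with Woolf standard error of the log OR,
  se = √(1/a + 1/b + 1/c + 1/d), Wald 95% CI exp(ln OR ± 1.96 se), and
  two-sided Wald p from z = ln OR / se. No continuity corrections by
  default (a Haldane 0.5 correction is opt-in for zero cells).
- **Genetic models**: codominant (heterozygote or variant homozygote vs
  reference homozygote), dominant (carrier vs non-carrier), recessive.
  The 3-genotype case/control distribution is compared with a 2-df
  Pearson chi-square; a Cochran–Armitage trend test is also provided.
- **HWE**: goodness-of-fit chi-square of control genotype counts against
  n(p², 2pq, q²) with q estimated by gene counting; 1 df. An exact
  (conditional enumeration) test is available as an alternative.
- **Adjusted ORs**: maximum-likelihood logistic regression of case status
  on the genotype contrast plus covariates (age continuous; sex, smoking,
  drinking binary; BMI and pack-years as category indicators).
- **Stratification**: per-stratum genetic-model estimates, Cochran's Q
  heterogeneity on stratum log ORs (inverse-variance weights), and
  likelihood-ratio tests for genotype × covariate interaction.
- **FPRP** (Wacholder et al.): FPRP = α(1−π) / [α(1−π) + (1−β)π] where α
  is the observed two-sided p at full precision, π the prior probability
  the association is real (grid 0.25 … 0.0001), and 1−β the power to
  detect a target OR of 1.50 (risk) or 0.67 (protective) given the
  estimate's standard error. An association is *noteworthy* when
  FPRP < 0.2 at prior 0.1.

## Worked example

```r
library(snpcc)
cnts <- gastric_genotype_counts()

hwe_chisq(cnts$rs2294008)
#> <hwe_result> rs2294008 q=0.2849 chi2=2.6251 df=1 p=0.1052

est <- crude_or(make_contrast(cnts$rs2274223, "het_vs_ref"))
est
#> <effect_estimate> AG vs AA: OR 1.43 (1.14-1.78), p 0.002 [crude]

fprp_grid(est, fprp_config(se_source = "counts"))
#> <fprp_result> AG vs AA: OR 1.43, p 0.002, power 0.948 vs OR1 1.50 [noteworthy]
#>   0.25    0.1   0.01  0.001 0.0001
#>  0.005  0.016  0.149  0.639  0.947

co <- gastric_fixture_cohort()          # subject-level reconstruction
risk_group_contrast(co)$estimate
#> <effect_estimate> 2-4 vs 0-1: OR 1.28 (1.04-1.57), p 0.020 [crude]
```

Reading: the control genotype distribution of rs2294008 is compatible
with HWE (p = 0.105, so no genotyping/population red flag); carrying one
G allele at rs2274223 raises stomach-cancer odds by an estimated 43%
(95% CI 14–78%), and the finding stays credible (FPRP 0.016 < 0.2) even
granting only a 1-in-10 prior that the association is real; carrying 2–4
of the panel's risk genotypes versus 0–1 raises the odds by 28%.

## Command line

```sh
SNPCC=$(Rscript -e 'cat(system.file("scripts/snpcc", package = "snpcc"))')
Rscript $SNPCC simulate --seed 17 --out subjects.tsv
Rscript $SNPCC report --subjects subjects.tsv --snp-config panel.json --out-dir out/
```

Subcommands: `simulate`, `hwe`, `assoc`, `profile`, `stratify`, `fprp`,
`report`; every table has a `--json` variant. Exit codes: 0 success,
2 validation error, 1 computational failure.

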