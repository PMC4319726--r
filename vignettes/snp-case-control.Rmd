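---
title: "Case-control SNP association with FPRP: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-control SNP association with FPRP: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpcc)
```

This vignette is the package's own account of its statistical content:
what each stage computes, which conventions were chosen where several are
in circulation, what the synthetic-data generator does and does not
emulate, and the known limitations — including the places where the
bundled study's printed tables are internally inconsistent.

## The design being analysed

The package targets the standard replication design for GWAS-identified
variants: unrelated cases with a confirmed diagnosis, cancer-free
controls frequency-matched on age and sex, a handful of candidate SNPs
genotyped in both groups, and subject-level covariates (age, sex,
smoking, pack-years, drinking, BMI, and for cases tumour site and stage).
Frequency matching is handled by covariate adjustment, not conditional
regression — there are no matched pairs.

The bundled example is a stomach-cancer study of 692 cases and 774
controls genotyped at *PSCA* rs2294008 C>T and rs2976392 G>A, *PLCE1*
rs2274223 A>G, and *MUC1* rs4072037 T>C. Only its printed aggregate
tables are carried; no subject-level data are included or required.

## Conventions and parameters

**Genotype labels.** Heterozygotes are canonicalized to *alphabetical*
allele order (`AG`, `CT`), not reference-allele-first. This is a
deliberate choice: association tables in this field label heterozygotes
alphabetically regardless of the reference/variant assignment (the
bundled study writes `AG` for its G>A SNP and `CT` for its T>C SNP).
Reference-first labelling would reproduce only half of those labels.

**Odds ratios.** Woolf SE, Wald CI and Wald p, with no continuity
correction anywhere by default — this reproduces every reproducible
printed value of the bundled study. A zero cell is a hard error that
names the opt-in Haldane 0.5 correction rather than silently applying it.

**The printed per-contrast p is the Wald p.** The study's per-row P
column agrees with the Wald test on ln(OR) at printed precision for all
nine whole-cohort contrasts; the Pearson 2×2 chi-square agrees with the
Wald p within 5×10⁻⁴ everywhere but rounds differently for one contrast
(0.0225 vs 0.0226). The package exposes both (`crude_or()$p` and
`chisq_2x2()`), and the "additive model" P printed beside 3-genotype
blocks is implemented as the 2-df genotype-distribution test, which
reproduces all four printed values (0.048/0.058/0.007/0.055); a
Cochran–Armitage trend test is provided but deliberately not labelled
"additive".

**HWE.** Goodness-of-fit chi-square with 1 df (3 cells − 1 − 1 estimated
allele frequency), no continuity correction; monomorphic input returns
χ² = 0, p = 1 by convention. The exact conditional test
(`hwe_exact()`) is available but is not the default because the
chi-square form is what reproduces the published control p-values.

**Covariate encoding** for adjusted models: age in years (continuous);
sex, smoking, drinking as binary indicators; BMI (under / normal / high,
cut points 18.5 and 24.0 kg/m²) and pack-years (none / ≤mean / >mean,
mean 27) as two indicators each. The source publication is silent on
encoding; the categorical presentation of its characteristics table
motivates categorical BMI. Within strata the stratifier is dropped from
the adjustment set (and smoking/pack-years drop each other — pack-years
is nested in smoking status), avoiding collinearity.

**Risk-genotype profile.** Per-SNP risk sets come from the panel
definition; note the *MUC1*-type case where the *reference homozygote* is
the risk genotype (its variant allele is protective). The published 0–1
vs 2–4 grouping is the default threshold (2 of 4), configurable. Subjects
missing any panel genotype are flagged incomplete and excluded from the
group contrast rather than imputed — conservative, and it preserves
printed totals.

**Heterogeneity and interaction.** The source text reports "heterogeneity
tests" and "no statistical evidence of interaction" without naming
methods. The package uses the two standard choices: Cochran's Q on
stratum log-ORs with inverse-variance weights (needs only per-stratum
estimates, so it works on published subgroup tables too), and
likelihood-ratio tests adding genotype × covariate product terms to the
adjusted logistic model (df = number of added terms). Tumour site and
stage exist only for cases, so those strata are case-only against the
full control group — exactly the structure the published subgroup table
implies by repeating the same control counts in every such stratum.

**FPRP.** FPRP = α(1−π) / [α(1−π) + (1−β)π]. Three conventions matter
and are fixed as follows:

* α is the observed two-sided p **at full precision**, never the rounded
  printed value — the published FPRP cells can only be reproduced this
  way;
* power is computed against a target OR of 1.50 (risk) or 0.67
  (protective, chosen by the direction of the observed OR) from the
  estimate's log-OR standard error, by default reconstructed from the CI
  (`se = (ln U − ln L)/(2 z)`), with a Woolf-from-counts alternative; the
  two routes agree within 0.002 on every bundled contrast;
* the power column uses a fixed two-sided α = 0.05. The study's own
  power recipe is **not recoverable**: no combination of SE source and α
  convention reproduces its printed power column (candidates span
  0.886–0.957 against a printed 0.919, for example). Printed power
  values are therefore treated as *inputs* when validating FPRP cells
  and are never asserted as outputs.

Noteworthiness is FPRP < 0.2 at the headline prior 0.1, both
configurable. Rendered tables print p and FPRP to 3 decimals and
"<0.0001" below 10⁻⁴; all computation is full precision.

## The synthetic-data generator

Two modes, because the two jobs are different:

* **Marginal mode** states each group's genotype and covariate
  distributions directly — defaults are the bundled study's margins,
  including its visible case-control imbalance in smoking, drinking and
  BMI (controls smoke and drink more; the control group is hospital
  visitors, not a population sample). With `exact = TRUE`,
  largest-remainder rounding plus a deterministic stride interleaving
  reproduces target counts exactly. This regenerates published tables;
  it makes no causal claim and its joint distribution across variables
  is artificial.
* **Causal mode** draws a population with HWE(q) genotypes and
  independent covariates, assigns disease by a logistic model
  (baseline odds 0.08 by default, per-genotype ORs relative to the
  reference homozygote, per-covariate-level ORs), then samples cases and
  controls to size. The generating truth is returned alongside, and
  `case_genotype_probs()` computes the implied case genotype margin
  analytically for cross-checks. Covariate effects default to neutral
  (OR 1) with population prevalences set to the control margins;
  confounding is injected explicitly, either through covariate ORs or
  through `q_levels` (allele frequency varying by a covariate level),
  which is what the parameter-recovery tests use.

Tight linkage between two SNPs is modelled by a copy-with-probability-ρ
shortcut, not a haplotype model — sufficient for pipeline testing, not
for LD inference. No population stratification, no genotyping error, no
missingness mechanisms are simulated; a green recovery test therefore
establishes estimator correctness under a clean generating model, not
robustness to those artefacts.

A counts-level fast path (`simulate_null_counts()`) draws per-SNP
multinomial genotype counts directly — the exact sampling law the
subject-level marginal generator induces per SNP — so that 10,000-replicate
calibration studies run in seconds; a test verifies the two paths agree
in distribution.

## Reconstructed subject-level fixture

`gastric_fixture_cohort()` rebuilds a deterministic 1,466-subject table
whose per-SNP genotype margins equal the printed counts exactly *and*
whose combined risk-genotype split equals the printed 288/404 (cases) and
369/405 (controls) low/high division. The joint assignment is a
Gale–Ryser realization of the carrier-indicator matrix with those row and
column sums; covariates are laid out to match the characteristics-table
margins with pack-years nested in smoking. It is synthetic: only
marginal/crude statistics computed from it are meaningful, which is why
adjusted ORs are validated on causal simulations instead.

## Known discrepancies in the source tables

Found while freezing test expectations; none are "fixed" silently —
each is either resolved by a documented rule or excluded with a comment:

1. The rs2294008 case genotype counts print as 332/309/61, which sum to
   702 ≠ 692 and contradict the printed 46.53%. The percentage-derived
   resolution 322/309/61 (`counts_from_percentages()`) restores the
   column total and reproduces the printed crude OR.
2. The rs2294008 CT upper CI prints 1.63; the Woolf bound from the
   resolved counts is 1.6246 → 1.62, and no counts consistent with the
   printed totals give 1.63. The corresponding acceptance check is left
   failing by design, with this analysis.
3. The rs4072037 dominant lower CI prints 0.62; its own counts give
   0.6147 → 0.61.
4. The FPRP row for the rs2274223 dominant contrast prints the same five
   cells as the codominant row above it despite different p and power —
   a transcription duplicate; recomputation from its own inputs differs
   by up to 0.007.
5. One FPRP cell (rs2274223 codominant, prior 0.001) reproduces only
   from a p carried at 2 significant figures; full-precision p moves it
   by 0.0026.

## Runtime choices in the test suite

The acceptance-grade simulations run at their stated sizes (M = 200,000
FPRP Monte Carlo; 10,000-replicate null calibration at the study size
n = 1,466; 100 causal replicates at n = 20,000). Module-level simulation
examples are scaled down (interaction type-I error at 120 replicates of
n = 1,000; power at 25 replicates of n = 10,000) with acceptance bands
widened to match the replicate count; all seeds are fixed, so the suite
is deterministic end to end.

## Limitations

No conditional or exact logistic regression, no Mantel–Haenszel pooling,
no multiple-testing adjustment (FPRP is the study design's answer to
multiplicity and is documented as such), no VCF/PLINK input, no genotype
QC or imputation, no haplotype inference, and no Bayesian false-discovery
alternatives. Adjusted ORs from the bundled study are not reproducible —
they require the original microdata — and are therefore validated only
by parameter recovery on synthetic cohorts.
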