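---
title: "Methods: candidate-SNP association, heterogeneity-aware meta-analysis and the counted BMI risk score in PCOS case-control data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: counted genetic risk scores for PCOS case-control studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcosgrs)
```

## The scientific question and the analysis chain

Polycystic ovary syndrome (PCOS) is strongly heritable, and most patients
carry excess weight. Because BMI itself is polygenic, any case-control scan
for PCOS genes risks picking up BMI loci simply because cases are heavier.
The design this package implements asks the converse question: *in
case-control sets where cases and controls have similar BMI, do established
BMI-raising alleles still shift PCOS risk?* A persistent effect would point
to pleiotropy (or to a single BMI measurement being a poor proxy for
lifetime exposure); a null supports treating BMI adjustment as a clean way
to deconfound PCOS genome scans.

The chain has six stages, each exposed as ordinary functions and driven by
the numbered scripts under `analysis/`:

1. **Phenotype definition.** Cases satisfy the Rotterdam 2003 rule: at
   least two of (a) oligo-/anovulation, (b) hyperandrogenism, (c)
   polycystic ovarian morphology (PCOM). `classify_rotterdam()` implements
   the thresholds literally: cycle length strictly over 35 days or
   amenorrhea; free androgen index FAI = 100·T/SHBG strictly above 4.5 *or*
   modified Ferriman-Gallwey score of at least 8 (inclusive); at least 12
   follicles in one ovary (inclusive, the maximum over the two ovaries) *or*
   ovarian volume strictly above 10 ml. Whether the follicle criterion
   should instead sum over ovaries is genuinely ambiguous in the criteria's
   phrasing; we read "in one or both ovaries" as a per-ovary threshold and
   take the maximum. Exclusion diagnoses (Cushing's disease, congenital
   adrenal hyperplasia) are a boolean veto on the record rather than a
   modelled quantity, and gonadotropin screening is likewise an optional
   exclusion flag: neither is measured in the synthetic data.
2. **Genotype QC.** Call rates per SNP and individual against a 0.95
   threshold (the study's genotyping success floor) and the Levene-Haldane
   exact Hardy-Weinberg test (`hwe_exact_test()`): conditional on the
   observed allele counts, the p-value sums the probabilities of all
   heterozygote counts no more probable than the observed one. Fractional
   imputed dosages are rounded to hard calls for HWE with a warning; the
   association stage uses them unrounded.
3. **Association.** `additive_logistic()`: maximum-likelihood logistic
   regression of status on risk-allele dosage, no covariates. The design
   matches on BMI instead of adjusting, so the unadjusted model is the
   primary analysis; BMI-stratified reruns (`bmi_stratify()`, threshold 30
   kg/m², boundary to the upper stratum) probe residual confounding within
   strata. Wald intervals use the multiplier 1.96 exactly, as published
   tables do. Monomorphic SNPs and separated fits are flagged
   non-estimable, never errors, so panel scans always complete.
4. **Meta-analysis.** Inverse-variance fixed effect with Cochran's Q and
   I² = max(0, (Q−df)/Q); when I² strictly exceeds 0.25 the combined
   estimate switches to DerSimonian-Laird random effects, with
   τ² = max(0, (Q−df)/(Σw − Σw²/Σw)) and weights 1/(se² + τ²). The random-
   effects estimator is deliberately the method-of-moments DL form — the
   conventional default — rather than REML or Paule-Mandel; published
   random-effects CIs computed with a different τ² estimator will differ
   slightly in width, which is why only the pooled point estimate of the
   heterogeneous SH2B1 SNP is treated as reproducible. `se_from_ci()`
   inverts printed OR (CI) rows to (log OR, SE) pairs so transcribed tables
   flow through the same pooling code as fresh fits; its `asymmetry`
   diagnostic quantifies how much two-decimal rounding has distorted the
   interval's symmetry.
5. **Counted genetic risk score.** Unweighted allele count over the
   12-SNP panel (maximum 24). Individuals genotyped for fewer than
   ceil(0.9 × 12) = 11 SNPs are excluded; remaining missing dosages are
   replaced by the SNP's mean observed dosage over that case-control set,
   cases and controls pooled ("total population" read per set — pooling
   across sets would let the much larger Dutch control sample impute into
   the UK set). Scores bin as <8, 8-9, 10-11, 12-13, 14-15, 16-17, ≥18.
   The top bin is printed elsewhere as ">18", which would leave a score of
   exactly 18 unassigned; assigning 18 upward is the only exhaustive,
   order-preserving reading. Fractional imputed scores bin by their integer
   part, preserving the allele-count semantics. The reference bin is the
   bin containing the mean control score; per-bin odds ratios against it
   use the Woolf 2×2 formula exp(ln(ad/bc) ± 1.96·√(1/a+1/b+1/c+1/d)),
   with the Haldane-Anscombe 0.5 added to all four cells of a comparison
   only when one cell is zero (flagged in the output). The unweighted count
   is a modelling choice, not a limitation: when per-allele effects are
   this small, weighting adds little and the equal-contribution assumption
   keeps the score interpretable as "number of BMI-raising alleles".
   The overall trend is a tie-corrected Kruskal-Wallis rank test of bin
   ordinal by status — with a binary outcome across seven ordered bins no
   other standard reading of a "trend test" exists, and since the original
   computation (raw vs binned scores) is not recoverable, printed trend
   p-values are treated as qualitative (significant / not), not as exact
   targets.
6. **Power.** `case_control_power()`: the 1-df allelic test under a
   multiplicative per-allele model. Case allele frequency
   p·OR/(p·OR+1−p); population-based controls keep the population
   frequency (the study's design — its control samples were general-
   population cohorts that may include undiagnosed cases), while the
   known-unaffected option depletes controls using a prevalence input.
   Power uses the two-proportion z-test on 2N alleles with pooled variance
   under the null and unpooled under the alternative. With population
   controls the prevalence never enters, which is why the unstated
   prevalence in the original power statement is immaterial here.

## The synthetic-cohort generator

No subject-level data are deposited for this design, so the generator is a
first-class module and defines the conditions everything is tested under:

* Genotypes: independent biallelic SNPs in Hardy-Weinberg proportions at
  the panel's risk-allele frequencies (0.21-0.84). Linkage disequilibrium
  is deliberately absent — the 12 loci sit on 10 chromosomes and the
  analysis treats them independently.
* Disease: logistic-additive on allele count,
  P(case|g) = logistic(ln(odds₀) + Σ g_j ln OR_j), with baseline odds 0.15
  — a plumbing constant, since odds-ratio recovery is invariant to
  prevalence. Cohorts are drawn to *exact* case/control quotas by rejection
  (cap 10⁷ draws), reproducing fixed published sample sizes: 563/791
  (UK-shaped) and 510/2720 (Dutch-shaped).
* Default per-allele ORs are 1.0: the null is the study's conclusion, and
  non-null effects (e.g. OR 1.3 for power and recovery checks) are set
  explicitly per experiment.
* Missingness: entry-wise independent at 5%, the complement of the ">95%
  genotyping success" statement.
* BMI: log-normal with median 26.3 and IQR ≈ 24-29 kg/m² (the reported
  control distribution), independent of genotype by default, so the
  BMI-matched design holds by construction.
* Phenotypes: criterion patterns drawn per individual (cases forced to ≥2
  criteria, controls to <2, at clinic-typical marginal rates), then
  quantitative measures placed on the correct side of each diagnostic
  threshold, so `classify_rotterdam()` reproduces simulated status exactly.
* Seeds: one global seed; each stochastic stage uses seed + a fixed offset
  (`derive_seed()`), so any stage reruns identically in isolation.

What the generator does **not** emulate — and hence what green tests do not
certify about real data: linkage disequilibrium and population
stratification; differential (status- or genotype-dependent) missingness;
imputation uncertainty structure in fractional dosages; control
contamination by undiagnosed cases (population controls make this real but
unquantified); genotype-BMI dependence (available only as an explicit
stress-test flag, off by default); and BMI matching achieved by recruitment
rather than by independence.

## Numerical choices

* Logistic fits run IRLS to tolerance 1e-12 so Wald SEs match closed forms
  (the Woolf SE on collapsible 2×2 designs) to better than 1e-6.
* Separation is detected post-fit (non-convergence, |β| > 25 or SE > 50)
  and flagged rather than "fixed" — candidate-SNP panels at these sample
  sizes should never legitimately separate.
* I² exactly at 0.25 keeps the fixed-effect model ("exceeds" is strict);
  Q ≤ df truncates both I² and τ² to zero, making DL collapse to the
  fixed-effect result exactly.
* The HWE test works in log-probabilities (lgamma) and sums terms within
  1e-10 of the observed probability to absorb floating-point ties.
* All printed-style intervals use 1.96, not qnorm(0.975), to mirror the
  convention of the tables this pipeline reproduces; both the multiplier
  and the I² threshold are arguments.

## Problem sizes in the test suite

The suite regenerates everything in code: binomial checks at n = 10⁵,
HWE/frequency convergence at n = 3,000-10,000, full-chain runs at a few
hundred individuals, parameter recovery over 100 seeded replicates at the
combined study size (1,073/3,511), empirical power over 2,000 replicates at
that size, and null size of the Wald test over 2,000 replicates of n = 5,000
— sizes chosen so each check has the resolution its tolerance needs.

## Known limitations

* Two-cohort meta-analysis is the designed use; the formulas accept any k,
  but no multi-cohort features (moderators, small-k corrections such as
  Hartung-Knapp) are provided.
* The trend test's exact correspondence to the original software's
  computation is unknowable (see above); only its qualitative behaviour is
  asserted.
* A single BMI measurement stands in for lifetime exposure, in the data
  this design targets as much as in the simulation; longitudinal dynamics
  are out of scope.
* No VCF/BED input, no strand flipping (A/T and C/G SNPs warn instead), no
  genotype imputation: imputed data enter only as precomputed fractional
  dosages.
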