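---
title: "Methods: tag-SNP imputation of a gene-deletion genotype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tag-SNP imputation of a gene-deletion genotype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deltag)
```

## The problem and the model

A 16-kb deletion removes the *KLRC2* gene (NKG2C receptor) from one or
both chromosomes, producing a three-state genotype — wt/wt, wt/del,
del/del — that `deltag` encodes as the deletion-allele dosage 0/1/2.
Direct typing needs a bespoke PCR assay; array-typed cohorts can instead
be imputed through SNPs in linkage disequilibrium (LD) with the
deletion. The pipeline is:

1. estimate r² between the deletion dosage and every SNP in the region
   and keep candidates with r² > 0.2;
2. train a random-forest classifier of the deletion genotype on the
   candidates and rank them by out-of-bag permutation importance;
3. re-train on the top 1..k panels and select the panel with the fewest
   misclassifications (ties: higher unweighted kappa, then fewer SNPs);
4. impute new cohorts with the selected panel, excluding samples with
   missing panel dosages;
5. sanity-check imputed cohorts (Hardy–Weinberg equilibrium) and carry
   the calls into case-control association.

The forest is the classifier rather than a parametric haplotype model
because the mapping from a handful of 0/1/2 dosages to a 3-class label
is an arbitrary discrete function with interactions; trees represent it
exactly, need no phasing, and provide an internally unbiased error
estimate through out-of-bag samples.

## LD estimators

Two estimators are provided, selected by `method` in `scan_ld()`:

* **`dosage` (default)** — the squared Pearson correlation of the two
  dosage vectors over pairwise-complete samples (the "composite" r²).
  The deletion genotype is unphased, and for unphased biallelic data
  this estimator is the conventional choice; it is symmetric and
  invariant to allele-label flips.
* **`em`** — maximises the two-locus multinomial likelihood over the
  four haplotype frequencies by EM, splitting double heterozygotes
  between cis and trans at each iteration, and returns
  r² = D²/(p_A q_A p_B q_B) at the fixed point. Convergence is declared
  when no haplotype frequency moves by more than 1e-10, with a 1000
  iteration cap (non-convergence returns the last iterate with a
  warning and `converged = FALSE`). The EM's margins equal the sample
  allele frequencies, so the likelihood has one effective free
  parameter; the test suite verifies the fixed point against an
  exhaustive grid search over that parameter.

Monomorphic vectors give an explicit undefined-LD error rather than
r² = 0: silently admitting a constant SNP as "uncorrelated" would let
monomorphic markers through the candidate filter. In `scan_ld()` such
SNPs are simply dropped from the scan. Ranking ties are broken by
ascending genomic position so output order is deterministic.

## Forest and panel selection

Hyperparameters (`forest_params()`) default to the cited
implementation's conventions: 500 trees, `mtry = floor(sqrt(p))`,
minimum node size 1, permutation importance, a required seed, and a
single compute thread so results are bit-reproducible. Missing candidate
dosages are median-imputed per SNP at training time (with a reported
count); at imputation time samples with missing panel dosages are
excluded instead — the behaviour wanted when deploying a fixed panel.

Panel evaluation supports two modes. `resubstitution` (default) compares
predictions on the training samples, matching how published
cross-tabulations of training-set agreement are built; `oob` uses
out-of-bag predictions and is the internally unbiased choice. Both are
reported in the selection table; selection itself uses whichever mode
the report was built with. Where an importance ranking disagrees with a
published panel's nesting order, `deltag` nests strictly by its own
importance ranking — the selection criterion (misclassifications, then
kappa, then parsimony) is what defines the panel, not the listing order.

## Agreement statistics

`cohen_kappa()` implements weighted kappa with identity, linear
(1 − |i−j|/(k−1)) and quadratic Fleiss–Cohen (1 − (i−j)²/(k−1)²)
weights. The "weighted" default in `agreement_report()` is quadratic
because, on the published 309-sample training table, quadratic weights
reproduce the printed weighted value (0.94) while linear weights give
0.92. The standard error is the large-sample Fleiss–Cohen–Everitt
asymptotic for an estimated kappa, and the 95% CI is κ ± 1.96·SE; the
test suite checks the SE against a 10,000-resample bootstrap of the
same table (they agree within 25%; published intervals built by other
variance variants can be mildly asymmetric around κ, which an
asymptotic normal interval cannot reproduce exactly).

## Population-genetic statistics

* **HWE** — a likelihood-ratio G test, G = 2 Σ O ln(O/E) with expected
  counts (q²n, 2pqn, p²n) and df = 1, used uniformly (no exact test:
  the validation workflow tests moderately large samples where the LRT
  is calibrated; the suite verifies empirical size 0.05 ± 0.015 at
  n = 500 under the null). A monomorphic sample is reported as G = 0.
* **Allele-level comparisons** — each genotype contributes two allele
  observations; group differences are fitted by logistic regression of
  allele state on population. For this saturated model the fitted ORs
  equal closed-form 2×2 allelic ORs (verified to 1e-8), so the
  regression adds only the overall LRT across groups. Treating the two
  alleles of one person as independent understates within-person
  correlation; intervals are therefore mildly anti-conservative. This
  construction is retained because it is the standard way published
  count tables are compared.
* **Case-control association** — `stats::glm` (IRLS) of the binary
  phenotype on genotype indicators (wt/wt reference) plus covariates;
  age and sex enter a priori, ethnicity optionally with the most
  frequent group as reference. Sex is coded with female = 1. The joint
  genotype test is a 2-df LRT against the covariates-only model.
  Complete-case analysis with a reported drop count; a warning fires
  below ~10 complete cases per parameter, and coefficients above 15 on
  the logit scale trigger a separation warning.
* **Power** — Monte-Carlo: control genotypes are drawn in HWE at the
  control allele frequency, case genotypes from the tilted distribution
  ∝ HWE(g)·OR^g, and each replicate is tested by the Wald z of the
  dosage-trend coefficient in a logistic fit. Assumptions (allele
  frequency, additive trend test) are explicit arguments because
  published power statements rarely state theirs.

## The simulator

`sim_config()` describes the synthetic cohorts used for validation. Per
sample, two haplotypes are drawn independently; on each haplotype the
deletion allele is Bernoulli(p_del) and every tag-SNP allele is drawn
conditionally on that haplotype's deletion allele from the two-locus
table f(del, alt) = p_del·p_alt + D, D = r·√(p_del q_del p_alt q_alt).
Specs violating the Lewontin bounds (any haplotype frequency < 0) are
rejected at configuration time. Tags are conditionally independent
given the deletion allele: this reproduces the dominant tag–deletion LD
structure without modelling full haplotype blocks, which is all the
classifier consumes. Noise SNPs are unlinked and in Hardy–Weinberg
proportions. Phenotypes follow a logistic model in age (uniform over
the configured range — a simplification; real cohort age distributions
are not uniform), sex, and genotype indicators.

Defaults encode the validation study's conditions: p_del = 0.36
(West-African adult cohort), three tags at r² = 0.937/0.889/0.888 (the
observed LD of the three best published tags) with tag alt-allele
frequency equal to p_del, 100 noise SNPs at frequencies U(0.05, 0.5),
ages U(30, 95), 71% female, age OR 1.07 per year, female OR 1.68,
genotype ORs 1 (the null association found for scarring), intercept
odds 0.025 (≈ balanced arms at the cohort's mean covariates), and seed
20160616. The truth record (per-sample true dosage, realized tag r²,
generating parameters) is attached to the cohort and written to
`truth.json` by `write_fixture()`, so any imputation output can be
scored without re-simulation.

What passing simulated tests shows — and what it does not: the
simulator draws panmictic, unrelated samples with exactly one causal LD
structure. Real cohorts add kinship, population structure, genotyping
batch effects, imputation uncertainty in the array data itself, and LD
between the candidate SNPs; accuracy measured here is therefore an
upper bound, and a panel should be re-validated before use in a
population distant from its training population.

## Validation problem sizes

The shipped test-and-acceptance workloads use: n = 2500 (training
simulation, 3 tags + 100 noise SNPs), n = 1000 (independent imputation
target), n = 5000 (association parameter recovery), 1000 replicates of
n = 800 (joint-LRT type-I calibration), 2000 replicates of n = 500 (HWE
null calibration), and 1000 Monte-Carlo replicates for power at the
published case/control sizes (1090/1531). These sizes keep every
stochastic check's Monte-Carlo error well inside its assertion band
while remaining desk-scale.

## Known limitations

* No kinship or population-structure correction anywhere; intended for
  the null-result and frequency-description analyses it accompanies.
* The EM estimator assumes random mating within the two-locus system;
  strong inbreeding would bias both estimators.
* Imputation quality is bounded by the realized tag LD; the monotone
  dependence of concordance on r is part of the test suite, but
  concordance claims only transfer to cohorts whose LD matches.
* Multi-allelic VCF records are skipped, not split, because the method
  operates on biallelic tag SNPs; no genotype-likelihood (GL/PL)
  handling.
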