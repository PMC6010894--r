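---
title: "Genetic correction of serum AFP: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic correction of serum AFP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gencorrect)
```

## The problem

Serum alpha-fetoprotein (AFP) is the standard screening biomarker for primary
hepatocellular carcinoma (HCC), but part of its inter-individual variation is
germline: common SNP alleles shift an individual's constitutive AFP level
without shifting their cancer risk. For risk prediction that heritable
component is measurement noise. `gencorrect` estimates it from a small SNP
panel and divides it out, then asks the downstream question that matters:
does the corrected marker predict incident disease better than the raw one?

## The correction model

Each panel SNP *s* has a **relative allelic effect** $a_s$: the multiplicative
factor on the biomarker per copy of the effect allele. It is estimated by
ordinary least squares of the natural-log biomarker on allele dosage
$d \in \{0,1,2\}$ and back-transformed, $\hat a = e^{\hat\beta}$
(`fit_allelic_effect()`). Natural logarithms are used throughout and the
back-transform is the plain exponential; no smearing/retransformation factor
is applied, because the corrected quantity is a ratio of individual level to
population-anchored genotype mean, for which the raw back-transformed slope is
the consistent choice.

Under the multiplicative model the genotypes act as $(1, a, a^2)$. These are
normalized by the population-mean effect
$$E = w_{OO} + w_{OX}\,a + w_{XX}\,a^2,$$
giving genotype effects $(1/E,\; a/E,\; a^2/E)$ for non-carriers,
heterozygotes and homozygous carriers, so that the weighted mean genotype
effect is exactly 1 and corrected values stay on the measured scale
(`genotype_effects()`). Two weight choices are supported:

* **HWE weights** $\big((1-p)^2,\, 2p(1-p),\, p^2\big)$ from the effect-allele
  frequency $p$ — the default for published panels, since it needs no
  individual-level data and is exactly reproducible;
* **empirical weights** — observed genotype proportions in the cohort at hand,
  which is what an analysis with access to its own genotype counts would
  naturally use.

The combined genetic factor is the product over the panel,
$G_i = \prod_s e_s(g_{is})$, with a missing genotype contributing a neutral 1
and a per-row flag (the participant is retained: "correction unavailable"
means "no correction", not exclusion). The corrected biomarker is
$\mathrm{AFP}_i / G_i$. No renormalization of the multi-SNP product is
performed: under linkage equilibrium the mean of a product of independent
mean-1 factors is itself $\approx 1$, which the test suite asserts on
simulated cohorts rather than forcing algebraically.

Effect-allele orientation is preserved as given: $a < 1$ encodes a decreasing
allele. The alternative — flipping to the other allele so that $a > 1$ always —
silently reorients published tables and was rejected.

### Rounded published inputs

A subtlety worth spelling out because it affects any attempt to reconcile the
package's output with a published table. If a table prints the allelic effect
and the genotype effects all rounded to 2 decimals, the printed row need not
be reproducible from the printed inputs. For the panel SNP with $p = 0.33$,
$a = 1.08$:

```{r table2}
genotype_effects(p = 0.33, a = 1.08, weights = "hwe")
```

which rounds to (0.95, 1.03, 1.11) — while an unrounded estimate near
$a = 1.075$, which *also* prints as 1.08, rounds to (0.95, 1.02, 1.10):

```{r table2b}
round(genotype_effects(p = 0.33, a = 1.075, weights = "hwe"), 2)
```

For this reason `snp_effect()` accepts genotype effects supplied from a
2-decimal table with a consistency tolerance of 0.01 (half-unit rounding on
both $a$ and the effects can move the ratio $e_{OX}/e_{OO}$ by up to about
0.01), and exact 2-decimal agreement with a printed row is not a meaningful
correctness criterion for the arithmetic. The second default panel SNP
illustrates a stronger version of the same issue: its published genotype
effects are inconsistent with the multiplicative normalization in either
allele orientation (the non-carrier and homozygote cells appear swapped), so
the package always computes effects from $(p, a)$ and never treats that row as
ground truth.

## The synthetic cohort

The generator (`simulate_cohort()`) reproduces the statistical structure the
method assumes, with defaults set to the study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_participants` | 9819 | cohort size |
| panel | rs12506899 (p 0.33, a 1.08); rs2251844 (p 0.47, a 1.10) | AFP SNPs |
| `afp_median` | 2.70 ng/mL | median of the log-normal AFP marginal |
| `log_noise_sd` | 1.0 | SD of ln-AFP residual |
| `detection_limit` | 0.005 ng/mL | assay floor, applied exactly |
| `baseline_incidence` | 0.00581 | marginal incident-HCC probability |
| `true_or_per_10` | 5.0 | generative OR per 10 ng/mL |

Genotypes are Binomial(2, $p$) per SNP (HWE, linkage equilibrium). Log AFP is
$\ln(\text{median}) + \sum_s d_s \ln a_s - c + \varepsilon$ with
$c = \sum_s \ln E_s$, so the multiplicative genetic term is exactly the
combined normalized factor $G$ and the configured median stays interpretable.
The observed value is floored at the detection limit. The outcome is Bernoulli
with $\operatorname{logit} P = \alpha + \ln(\mathrm{OR}_{10})\, x/10$ where
$x$ is the **genotype-free** component of AFP and $\alpha$ is solved
numerically (to 1e-6) for the requested marginal incidence. Driving risk by
the genotype-free component makes the genetic factor pure multiplicative noise
in the measured biomarker — precisely the situation the correction is designed
to undo, and the generative truth behind the directional-improvement property.
Covariates (age, sex, BMI, smoking, drinking, marriage, education, physical
activity, family history) are drawn independently at their published marginal
prevalences/moments; they exercise the adjusted-model plumbing and do not
encode confounding.

The residual SD of log-AFP is not a published quantity; 1.0 is a deliberate
free-parameter default giving a right-skewed marginal (median 2.70, IQR
roughly 1.3–5.2 ng/mL) of the same order as the published IQR (0.98–3.90),
which the generator does not attempt to match exactly.

What the generator does **not** emulate — and hence what passing tests do not
establish about real data: linkage disequilibrium within the panel, population
stratification, genotyping error, covariate–outcome and covariate–genotype
dependence, secular changes in assay calibration, and non-log-normal tails of
true AFP in pre-clinical disease. Results on synthetic cohorts validate the
machinery and its statistical calibration, not the clinical effect size.

## Risk models and discrimination

`fit_logistic()` is maximum-likelihood logistic regression (IRLS via
`stats::glm`, convergence tightened to 1e-10) with the exposure scaled to per
10 ng/mL; reporting is Wald (OR, 95% CI as $e^{\hat\beta \pm 1.96\,SE}$,
two-sided p), the standard epidemiological convention; profile-likelihood
intervals are deliberately not used. Covariates are coded as 0/1 indicators
for the binary variables and continuous for age and BMI. The model battery
fits 2 exposures × 3 nested covariate sets; the subgroup analysis refits the
fully adjusted model within sex, age (<62 / ≥62, `>=` on the upper stratum so
the partition is exhaustive and disjoint), BMI (<24 / ≥24), smoking and
drinking strata, dropping the stratifier from the covariate set. Degenerate
strata (under 50 rows, or one outcome class) are reported as NA rows. No
multiple-testing adjustment is applied across models or subgroups. Logistic
(not time-to-event) regression is retained deliberately, matching the design
being emulated. A hand-rolled Newton–Raphson optimizer in the test suite
serves as the independent oracle for the MLE.

The ROC layer is nonparametric throughout: the AUC is the midrank
Mann–Whitney estimator (ties count ½ everywhere, consistent with the pairwise
kernel); variances and the paired AUC-difference test come from placement
values — case $i$'s mean kernel against all controls and vice versa — whose
variances and paired covariance give the DeLong-type
$\operatorname{var}(\Delta)$, $z = \Delta/\sqrt{\operatorname{var}(\Delta)}$
and a two-sided normal p. When the two scores are rank-identical the
difference is exactly zero and p is reported as 1. Operating points use the
Youden index (sensitivity + specificity − 1), ties broken toward the higher
threshold (higher specificity); the published analysis did not name its rule,
and Youden is the reproducible standard choice. "Relative improvement" is the
relative percent change $100(\mathrm{AUC}_b - \mathrm{AUC}_a)/\mathrm{AUC}_a$
— the only reading consistent with published AUC pairs described as an
"18.8-point" gain — with the absolute difference also available from
`delong_compare()`.

## Numerical conventions

* Quantiles are type-7 (linear interpolation between order statistics), stated
  because IQRs are reported.
* Table-style rounding is half-up (5.805 → 5.81), matching how published
  tables print; internal computation is never rounded.
* All randomness flows from one master seed through `derive_seeds()`, so
  adding a pipeline stage does not perturb another stage's draws, and a
  `(config, seed)` pair reproduces a cohort bit-for-bit.
* Constructed genotype effects must satisfy $e_{OX}/e_{OO} = a$ and
  $e_{XX}/e_{OO} = a^2$ to 1e-12 and mean-1 to 1e-9; published 2-dp inputs to
  0.01 and 0.02 respectively (rounding propagation, above).

## Problem sizes used in the test suite

Simulation-based properties run at sizes chosen to make the sampling error of
the check at least threefold smaller than the tolerance being asserted:
allelic-effect recovery at n = 50 000 over 100 seeds (±0.02 for ≥95% of
estimates); OR recovery at n = 100 000; Wald-CI and DeLong-CI coverage at 200
and 1000 replicates; paired-test type-I error over 2000 null replicates at
100 cases/100 controls (accepted band 0.035–0.065 at α = 0.05). The
directional-improvement property scales the allelic effects up to 2.0 per
allele — making the genetic component ≈30% of log-AFP variance — because at
the study's true effects (8–10% per allele against log-SD 1.0) the expected
AUC gain is far below per-cohort sampling noise; the scaled runs establish the
direction and the paired test's power, not the clinical magnitude.

## Known limitations

* The correction assumes the panel's allelic effects are estimated in
  disease-free individuals of the same population; transported effects
  (different ancestry, different assay) will mis-normalize.
* HWE normalization is only as good as the HWE assumption; for cohorts with
  known departures use `weights = "empirical"`.
* The paired AUC test is asymptotic; with very few cases (tens) the normal
  approximation for the difference can be anticonservative, and a bootstrap
  would be preferable.
* Subgroup ORs inherit all the usual caveats of post-hoc stratification; the
  package deliberately reports them without multiplicity adjustment, as the
  emulated design does.
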