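# gencorrect

Genetic correction of a serum tumor biomarker — alpha-fetoprotein (AFP), the
standard screening marker for primary hepatocellular carcinoma (HCC) — and
evaluation of whether the corrected marker predicts incident disease better
than the raw measurement. It is written for epidemiologists and biostatisticians
who want to apply, or stress-test, biomarker correction by common germline
variants in a prospective-cohort setting.

Part of the variation in serum AFP between healthy individuals is heritable:
carriers of certain common SNP alleles run constitutively higher or lower AFP
without any change in disease risk. That heritable component inflates the
biomarker's noise as a risk predictor. `gencorrect` removes it.

## The model

For each SNP *s* in a panel, a relative allelic effect *a*<sub>s</sub> is the
multiplicative factor on the biomarker per copy of the effect allele, estimated
by ordinary least squares of ln(AFP) on allele dosage and back-transformed
(*a* = e<sup>slope</sup>). Under the multiplicative model the three genotypes
act as factors (1, *a*, *a*²); these are normalized by the population-mean
effect

&nbsp;&nbsp;&nbsp;&nbsp;*E* = (1−*p*)² + 2*p*(1−*p*)·*a* + *p*²·*a*²

(Hardy–Weinberg weights at effect-allele frequency *p*, or empirical genotype
proportions), giving genotype effects (1/*E*, *a*/*E*, *a*²/*E*) whose
population mean is exactly 1. An individual's combined genetic factor *G* is
the product of their per-SNP genotype effects (missing genotypes contribute a
neutral 1 and are flagged), and

&nbsp;&nbsp;&nbsp;&nbsp;AFP<sub>corrected</sub> = AFP<sub>measured</sub> / *G*.

Downstream, the package fits unconditional logistic regression (odds ratio per
10 ng/mL, Wald 95% CI) under three nested covariate sets and within five
subgroup splits, and compares the discriminatory ability of raw vs corrected
AFP with midrank (Mann–Whitney) AUCs, placement-value (DeLong-type) variances,
a paired nonparametric AUC-difference test, and Youden operating points. A
synthetic-cohort generator reproduces the statistical structure of the study
population (HWE genotypes, log-normal AFP with a 0.005 ng/mL assay floor, rare
incident outcome, published covariate marginals) so every stage is testable
without access to cohort data.

## Worked example

```r
library(gencorrect)

genotype_effects(p = 0.33, a = 1.08, weights = "hwe")
#>      e_OO      e_OX      e_XX
#> 0.9492196 1.0251572 1.1071698      (attr "mean_effect": E = 1.053497)

cohort <- simulate_cohort(sim_config(), seed = 20180425)   # n = 9819
corr   <- cohort_correction(cohort, afp_snp_panel(), weights = "hwe")
corr
#> <cohort_correction> 9819 participants, 2 SNPs, hwe weights
#>   original  mean 4.450  median 2.704 (IQR 1.341-5.249)
#>   corrected mean 4.452  median 2.709 (IQR 1.349-5.251)
#>   relative change in mean: -0.0% lower after correction

cohort$afp_corrected_ng_ml <- corr$result$corrected
run_model_battery(cohort)[, c("exposure", "model", "or_", "ci_low", "ci_high")]
#>        exposure  model      or_   ci_low  ci_high
#> 1           afp model1 4.691125 3.852198 5.712753
#> ...                                               (6 rows)
delong_compare(cohort$afp_ng_ml, cohort$afp_corrected_ng_ml, cohort$hcc)
#> <roc_comparison> AUC 0.843 vs 0.843, delta +0.0010 (+0.1%), z = 0.448, p = 0.6538
```

The first call shows the normalization itself: a variant with effect-allele
frequency 0.33 whose each allele raises AFP by 8% gives non-carriers a factor
0.95, heterozygotes 1.03 and homozygotes 1.11 once the population mean is
anchored at 1. In the simulated cohort the correction barely moves the mean
(the genetic factor has mean 1 by construction) but strips the dosage signal
from the corrected values; at the study's small allelic effects (8–10% per
allele against a log-residual SD of 1) the AUC gain is correspondingly small —
the directional property is established by the scaled-up simulations in the
test suite.

The full workflow is the four numbered drivers:

```sh
Rscript analysis/01_simulate.R            # cohort + descriptives
Rscript analysis/02_genetic_correction.R  # SNP effects + corrected AFP
Rscript analysis/03_risk_models.R         # OR tables, main + subgroups
Rscript analysis/04_discrimination.R      # AUCs, paired comparison, ROC curves
```

Each writes its tables under `results/` and prints a short narrative of what it
found.

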