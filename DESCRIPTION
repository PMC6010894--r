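Package: gencorrect
Title: Genetic Correction of Serum Tumor Biomarkers for Cancer Risk Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Corrects a serum tumor biomarker (alpha-fetoprotein, AFP) for
    common germline variation: per-SNP multiplicative genotype effects are
    estimated on the log scale, normalized so the population-mean effect is 1
    under Hardy-Weinberg equilibrium (or empirical genotype weights), combined
    multiplicatively across a SNP panel, and used to divide the measured
    biomarker. Downstream analyses mirror a prospective-cohort workflow:
    unconditional logistic regression (odds ratio per 10 ng/mL) under nested
    covariate sets and subgroups, and paired nonparametric (DeLong-type)
    comparison of ROC AUCs for raw versus corrected biomarker, including
    placement-value variances, Youden operating points and relative-improvement
    summaries. A synthetic-cohort generator with the statistical structure the
    method assumes makes every stage testable without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
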