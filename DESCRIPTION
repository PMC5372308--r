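Package: metamir
Title: Integrated Meta-Analysis of miRNA Differential Expression with
    Biomarker, Survival and Enrichment Stages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Cross-study integration of two-class miRNA expression cohorts:
    per-study moderated t-statistics with a variance-stabilizing fudge
    constant, Fisher combination of permutation p-values with one-sided
    direction classification, and standardized-mean-difference pooling under
    fixed- and random-effects (DerSimonian-Laird) models.  Downstream stages
    cover diagnostic-marker evaluation (empirical ROC/AUC, linear risk-score
    panels, Pearson correlation, relative qPCR quantification), prognosis
    (Kaplan-Meier, log-rank, Cox proportional hazards with univariate
    screening and stepwise selection), and miRNA target-set consensus with
    hypergeometric pathway enrichment.  A synthetic multi-study generator
    with planted differential expression, study-level baseline shifts and
    censored survival outcomes makes every stage testable without external
    cohort downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    survival,
    metafor,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
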