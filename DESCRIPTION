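Package: bioperturb
Title: Systemic Biochemical Perturbation Profiling of Biomarker Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for case-control biomarker panel studies of
    pediatric hepatic steatosis and similar two-group clinical cohorts.
    Implements nonparametric univariate screening with Holm-Bonferroni
    control, Ward hierarchical clustering with bootstrap support, per-group
    Spearman correlation networks, the Degree of Biochemical Perturbation
    (DBP) score, a sparse canonical-correlation discriminant, and a
    logistic-regression/ROC association chain, together with a synthetic
    cohort generator that emulates the statistical structure such studies
    assume (log-normal markers, group-specific location shifts and
    correlation structure, an ordinal severity-grade effect).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
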