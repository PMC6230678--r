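Package: fiscope
Title: Transcriptome-Based Identification of Eosinophilic Esophagitis
    Patients with Food Impactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for identifying the food-impaction (FI)
    subpopulation of eosinophilic esophagitis (EoE) patients from targeted
    esophageal mRNA panels. Implements NanoString-style count normalization
    (background subtraction and two-stage geometric-mean scaling to positive
    controls and housekeeping genes), three-group Kruskal-Wallis testing with
    Dunn's post-hoc comparisons, a weighted composite FI-score with an
    ROC-derived cutoff and Hanley-McNeil standard errors, exact two-by-two
    cohort statistics, and the multi-loop diagnostic gating that layers the
    FI loop onto an EoE probability gate. A seeded negative-binomial cohort
    simulator with planted group effects makes every stage testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
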