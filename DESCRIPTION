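Package: boxtask
Title: Simulation and Analysis of the Box Task Visuospatial Working Memory Paradigm
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Implements the Box Task, a computerised self-ordered search test
    of visuospatial working memory, as a fully simulated analysis pipeline:
    a task engine with a canonical session-log data model, scoring of
    between-search errors, within-search errors, completion time and the
    normalised Levenshtein search-path strategy score, parametric cognitive
    agents that generate synthetic control, behavioural-variant
    frontotemporal dementia (bvFTD) and Alzheimer's disease (AD) cohorts
    with coupled neuropsychological covariates, a published fixed diagnostic
    decision tree plus a simplified CHAID induction algorithm, ROC/AUC
    evaluation, Benjamini-Hochberg false discovery rate control,
    standardised-beta multiple regression and permutation-based group
    contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
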