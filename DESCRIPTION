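Package: codep
Title: Drug-Gene Co-Dependency Discovery and Translational Validation
Version: 0.1.0
Authors@R: person("codep", "maintainers", email = "codep@example.org",
    role = c("aut", "cre"))
Description: Integrative pharmacogenomic analysis of matched drug-sensitivity
    (AUC) and CRISPR gene-dependency screens. Nominates drug-gene
    co-dependencies with nested linear models and the gain in explained
    variance (delta R-squared), assesses them by permutation,
    leave-one-line-out, and random-specificity tests, validates co-target
    expression against ex vivo drug response in primary-specimen cohorts,
    evaluates composite two-gene expression signatures with Kaplan-Meier,
    Cox proportional-hazards, and IPCW time-dependent ROC analysis, projects
    signatures onto labelled single-cell atlases, ranks the genome-wide
    correlation landscape, and scores preranked gene-set enrichment and
    simplified regulon activity. Ships a seeded synthetic-data generator
    that emulates the statistical structure of every input, so the whole
    pipeline is testable offline.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
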