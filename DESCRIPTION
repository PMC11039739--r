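Package: modscreen
Title: Pooled CRISPR Drug-Modifier Screen Analysis with Expression Triage,
    Loewe Synergy and Survival Utilities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis chain for pooled CRISPR knockout drug-modifier screens
    in neuroblastoma and their downstream follow-up: sgRNA count
    normalization and sample-level QC, fold-difference hit calling with
    cross-drug intersection and recurrence ranking, quantile-normalized
    differential expression with a gene-set enrichment (GSEA) engine and
    permutation NES, miRNA target triage combining prediction-score cutoffs
    with dual-cell-line downregulation, four-parameter logistic dose-response
    fitting with Loewe-additivity synergy scoring, and expression-cutoff
    Kaplan-Meier/log-rank survival analysis. Ships seeded synthetic-data
    generators with planted ground truth so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    survival,
    limma,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
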