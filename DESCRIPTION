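Package: ataxic
Title: Transcriptomic Perturbation Heterogeneity Scoring for Single Cancer Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies the heterogeneity of transcriptomic perturbations in
    single cancer cells. The ATAXIC score of a cell is the sample standard
    deviation, across genes, of the absolute per-gene z-scored expression
    values, measuring how asynchronously the cell's genes deviate from the
    population mean. Includes scRNA-seq quality-control filters (minimum
    expressed genes, mitochondrial fraction, minimum cells per patient),
    log2(TPM+1) normalization, mean-expression signature enrichment scores,
    association statistics (Spearman correlation with Benjamini-Hochberg FDR,
    one-tailed Mann-Whitney U, Shapiro-Wilk normality checks, a compound
    viability screen), a seeded synthetic-cohort generator with per-cell
    ground-truth asynchrony, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    graphics,
    Matrix,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
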