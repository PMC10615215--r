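Package: crisprifit
Title: Fitness Scoring and Guide Design for Pooled CRISPRi Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for pooled CRISPR interference (CRISPRi)
    competition screens in bacteria. Covers rule-based sgRNA library design
    (protospacer scan with composition, seed and off-target filters),
    simulation of turbidostat competition with multinomial sequencing noise,
    count normalization and log2 fold-change estimation, area-under-the-curve
    fitness scores per sgRNA, correlation- and efficacy-weighted gene-level
    fitness, Wilcoxon/Benjamini-Hochberg hit calling with a combined
    significance score, condition-effect regression, and a sequence-feature
    harness for predicting sgRNA repression efficacy with position-wise
    importance and logo analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    limma,
    pracma,
    randomForest,
    xgboost,
    e1071,
    nnet,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
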