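Package: cdei
Title: Drug Efficiency Scoring from Pathway Perturbation Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Scores how far a drug or botanical extract moves a pathological
    transcriptome back toward the control state. Gene-by-sample expression
    matrices from a three-condition design (control, untreated case, treated
    case) are converted into per-pathway perturbation scores by signaling
    pathway impact analysis (SPIA) over signed gene-interaction graphs,
    aggregated per pathway with a replicate sign-consistency weight,
    summarized per dataset with a one-sample t statistic, and combined into a
    drug efficiency index in [-1, 1] used to rank treatments. Includes a
    synthetic-data generator for three-condition designs with
    pathway-structured perturbation and a tunable restoration fraction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    S4Vectors,
    SummarizedExperiment,
    DESeq2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
biocViews: GeneExpression, Pathways, GraphAndNetwork, Network,
    DifferentialExpression, Transcriptomics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
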