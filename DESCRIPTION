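Package: regulonboost
Title: Boosted Regulatory-Network Inference for Stress-Response Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing dose-response stress expression experiments in
    model organisms and inferring the transcription-factor circuitry behind
    them. Covers gene-level differential expression from normalised
    log-intensity microarray matrices (probeset collapse, one-way ANOVA,
    Benjamini-Hochberg FDR), Gene Ontology term enrichment by Yates-corrected
    chi-square against a fixed gene universe, cross-dataset overlap statistics
    (Venn partitions, hypergeometric tests, dose-response monotonicity), and a
    MEDUSA-style confidence-rated boosting learner that predicts discretised
    expression from promoter k-mer features and candidate regulator states.
    Transcription-factor importance is scored by model ablation, aggregated
    into a multi-run consensus, and exported as a regulatory network. Includes
    planted-network and expression simulators so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    Biostrings,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
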