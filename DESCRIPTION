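Package: xksilence
Title: Cross-Kingdom Small RNA Silencing Inference from Dual RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for inferring endogenous and cross-kingdom
    microRNA-mediated gene silencing between two interacting species
    (a biocontrol fungus and plant roots) from dual small-RNA and mRNA
    sequencing. Implements small-RNA read triage (length filtering,
    structural-RNA removal, collapsing, two-species partitioning by
    approximate substring matching), approximate-match quantification of
    mature miRNAs, negative-binomial differential expression with
    median-of-ratios normalization, hypergeometric term enrichment,
    consensus miRNA target filtering with opposite-expression and
    anticorrelation-versus-background tests, descriptive small-RNA
    summaries (length and 5' nucleotide profiles, antisense percentile
    rank analysis, qPCR quantities), and a fully specified two-species
    synthetic data generator with a ground-truth manifest for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
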