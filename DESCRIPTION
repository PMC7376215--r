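Package: oxripseq
Title: 8-oxoG RIP-Seq Enrichment Inference and Bench Assay Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers transcripts carrying oxidative 8-oxo-7,8-dihydroguanine
    (8-oxoG) marks from RNA-immunoprecipitation sequencing (RIP-seq) count
    data. Implements median-of-ratios normalization, method-of-moments
    negative-binomial dispersion estimation, per-transcript Wald tests of
    immunoprecipitated versus input libraries, Benjamini-Hochberg false
    discovery control, discrimination of exposure-induced oxidized
    transcripts by uniqueness or enrichment fold-change ratio,
    expression-bin selectivity profiling, and gene-set over-representation
    with a combined significance/deviation score. Also provides the
    quantification arithmetic for the accompanying bench assays:
    competitive ELISA standard curves (logit-log linearization,
    cross-reactivity correction, dilution concordance), immunoprecipitation
    efficiency from scintillation counts, dot-blot dose linearity,
    reverse-transcription truncation indices, and densitometry loading
    normalization. A seeded negative-binomial simulator with planted
    ground truth supports end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
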