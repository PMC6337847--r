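Package: snipchip
Title: Same-Species Spike-In Normalization for ChIP-Seq Using SNP-Based
    Read Classification
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative scaling of ChIP-seq experiments using spike-in
    chromatin from a second strain of the same species. Sequencing reads
    are assigned to the test or the spike-in genome by unique, perfect
    matches over intra-species SNPs on a concatenated hybrid reference;
    per-sample spike-in quotients (Q = C_spike/C_endo) yield a
    normalization factor (Nf = Q_Input/Q_ChIP) that places signal tracks
    from different conditions on a common, spike-in-anchored scale.
    Includes four estimator variants (read counts and three mean-pileup
    scores), depth-subsampling and spike-in titration robustness
    analyses, and a fully seeded synthetic-experiment simulator with
    closed-form expected values for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
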