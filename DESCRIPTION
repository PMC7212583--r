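Package: pwmbench
Title: All-Against-All Benchmarking of Transcription Factor Binding Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Benchmarks position weight matrix (PWM) models of
    transcription factor binding specificity against experimental
    reference data using three protocols: discrimination of ChIP-seq
    peak regions from nearby genomic controls (AUC ROC on sum occupancy
    scores), discrimination of HT-SELEX-enriched reads from shuffled
    controls with barcode/primer-extended inserts and top-percentile
    score cut-offs, and correlation of log sum occupancy scores with
    normalized protein-binding microarray (PBM) probe intensities.
    Per-experiment performance values are aggregated by geometric-mean
    rank scores to pick the best-performing matrix per factor, summarised
    in family-level cross-performance tables, and contrasted with
    benchmark-blind motif clustering based on word-set Jaccard distances
    and UPGMA. Includes parsers for MEME and CIS-BP motif formats and
    seeded synthetic-data generators with planted ground truth for all
    three assay types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
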