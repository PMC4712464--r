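Package: cnvscreen
Title: Screening, Annotation and Benchmarking of Exome CNV Predictions
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Post-processing of copy-number variant (CNV) calls predicted
    from exome read-depth programs (ExomeCopy, ExCopyDepth, ExomeDepth,
    CoNIFER, XHMM or any tabular caller). Screens calls against an in-house
    CNV database built from the reference exome collection, reporting for
    each query the number of reference samples carrying an overlapping call
    (database CNV count) and the median quality score of those calls (CNVQ),
    which flags recurrent coverage artifacts. Annotates calls from gene,
    conservation, dosage-sensitivity, known-CNV and clinical interval
    tracks using a 1-bp minimum-overlap rule, filters to rare high-quality
    candidates with low/high stringency presets, and benchmarks predictions
    against array-CGH truth sets (cumulative TP/FP curves, false discovery
    rate, FP/TP ratio and CNVQ-ratio tables). Includes a seeded synthetic
    fixture generator that emulates every input format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
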