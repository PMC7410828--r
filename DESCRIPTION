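Package: ccregistry
Title: Building and Classifying a Registry of Candidate cis-Regulatory Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives a registry of candidate cis-regulatory elements (cCREs)
    from per-biosample DNase peak calls and DNase/H3K4me3/H3K27ac/CTCF signal
    tracks. DNase peaks pooled across experiments are filtered on signal,
    width and FDR and reduced by greedy highest-signal selection to a set of
    non-overlapping representative DNase hypersensitive sites (rDHSs).
    Epigenomic signals averaged over each rDHS are normalized to
    within-biosample Z-scores of log10 signal, reduced to per-assay maximum
    Z-scores across biosamples, and used to promote rDHSs to cCREs and
    classify them into promoter-like, proximal and distal enhancer-like,
    DNase-H3K4me3 and CTCF-only groups, with per-biosample classifications
    and confidence tiers that account for missing assays. Includes a
    synthetic-data generator that plants elements of known class in a toy
    genome so every stage can be benchmarked against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics,
    rtracklayer,
    yaml,
    jsonlite,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
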