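Package: cnrqc
Title: Quality Control for CUT&RUN and Related Enrichment Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quality-control workflow for CUT&RUN, ChIP-seq and other
    sequence-enrichment assays. From coordinate-sorted BAM files and peak
    calls (ENCODE narrowPeak, broadPeak, or SEACR bed) it computes mapped-read
    counts, peak counts with q-value filtering, FRiP scores, consensus peak
    sets with overlap summaries (binary membership, upset and venn counts,
    Jaccard), genome-wide binned read-count correlations, RPM-normalized
    signal matrices over consensus regions with k-means clustering and
    IgG-control artifact flagging, and strand cross-correlation profiles with
    fragment-length estimation and read-length (phantom peak) artifact
    detection. Results are written as a CSV QC report plus plot-ready tables.
    A fully synthetic, ground-truth-annotated fixture generator (mini-genome,
    aligned reads, peak files in all three dialects) makes every component
    testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Rsamtools,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    rtracklayer,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
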