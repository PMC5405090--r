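Package: seqreg
Title: Sequential Transcriptional Activity from Time-Series RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the timing of transcription-factor activity from
    time-series RNA-seq counts and a curated table of regulator-target
    pairs. Counts are normalized with median-of-ratios size factors and
    log transformed; for each regulatory pair the lag between regulator
    and target expression is estimated by maximizing the absolute
    cross-correlation over candidate index shifts, pairs whose target
    would precede its regulator are discarded, and activation times are
    assigned by matching adjacent-timepoint expression differences
    through a pairwise-difference matrix. Retained, time-annotated pairs
    are assembled into a directed temporal network (self-loops allowed)
    exportable to GraphML and JSON with per-hour activity snapshots. A
    seeded synthetic-data generator with implanted lags and activation
    times supports end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    S4Vectors,
    optparse
Config/testthat/edition: 3
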