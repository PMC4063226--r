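Package: pvtplan
Title: Execution Planning for Pipelined Spliced-Alignment Workflows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for planning pipelined and distributed execution of
    spliced-alignment workflows over next-generation sequencing data. Provides
    a timing model for serial versus host/remote pipelined execution of
    paired-end read analysis (effective block times under a max-of-paths rule,
    totals, and percentage improvement), chromosome-balanced scatter/gather
    operators for parallel junction discovery (longest-processing-time
    partitioning of chromosomes, SAM record splitting, BED junction merging),
    a discrete-event simulator for a five-stage pipeline with two alternating
    inter-stage buffers (schedule, makespan, speedup), a linear
    execution-time-versus-read-count runtime predictor, and seeded synthetic
    fixture generators with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
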