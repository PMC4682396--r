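Package: bsmerge
Title: Consensus Methylation Calling from Multiple Bisulfite-Read Mappers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Merges per-cytosine methylation calls produced by several
    bisulfite-read mappers (Bismark, BSMAP, BS-seeker2 or any tool emitting
    a compatible per-cytosine table) into consensus methylation levels using
    three schemes: the plain average (Ave), a read-depth weighted average
    (wAve) and a Poisson depth-probability weighted average (pwAve), with a
    minimum-covering-mapper constraint. Ships a bisulfite read simulator
    with block-wise methylation truth and a statistical mapper emulator so
    the consensus schemes can be benchmarked against known ground truth
    (detection accuracy and detected amount of cytosines), plus multi-sample
    block binning, Spearman-distance hierarchical clustering and Newick
    export for cohort comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    ape,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
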