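Package: intronret
Title: Differential Intron Retention Analysis and Rule-Based Splice Competence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies intron retention from RNA-seq read placements as an
    RPKM-based retention index (intron RPKM over exonic transcript RPKM),
    computes knockdown versus control retention fold changes, classifies
    introns by transcript architecture (first introns, large flanking
    introns, polypyrimidine-tract quality) and tests group retention shifts
    with Wilcoxon rank-sum statistics. Includes a rule-based model of intron
    splice competence (polypyrimidine-tract quality, intron length, distance
    to a flanking exon junction complex deposition site) and a synthetic
    RNA-seq generator with planted per-intron retention truth so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
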