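Package: PsoraSeq
Title: Genome-Wide DNA Supercoiling Landscapes from Psoralen Pulldown Sequencing
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Turns psoralen-pulldown/input sequencing counts into a binned
    supercoiling landscape of a circular bacterial chromosome. Implements
    1-kb binning with repeat-region imputation, genome-average normalization,
    log2 pulldown/input enrichment and z-scoring; quantifies transcription
    twin-domains around co-oriented transcription units by expanding-window
    linear regression (amplitude and magnitude from the y- and x-intercepts);
    predicts the genome supercoiling landscape from a transcriptome by summing
    triangular per-operon twin-domains scaled by relative transcription rate;
    and analyzes large-scale replichore symmetry, macrodomain statistics and
    signal-defined region associations. A seeded synthetic-data generator
    produces ground-truthed pulldown/input count tracks with an ori-to-ter
    copy-number gradient and Poisson sampling noise so every stage is testable
    without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    yaml,
    jsonlite,
    e1071,
    S4Vectors,
    BiocGenerics,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Epigenetics, Coverage, Sequencing, Software
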