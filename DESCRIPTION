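Package: terminR
Title: Transcript 3'-Terminus Detection from Read-Start Pileups in Bacterial RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects transcript 3' termini in bacterial RNAtag-seq (and
    term-seq) data from the characteristic accumulation of read starts at
    fragment 3' ends. Provides strand-specific read-start extraction from
    mapped reads, a scaled local-readthrough statistic with negative-binomial
    peak testing across replicate libraries, classification of termini against
    gene and transcription-unit annotation, a library-preparation simulator
    for generating synthetic benchmark data, dataset overlap statistics, and
    downstream analyses of 3' UTR expression outliers, condition-specific
    readthrough, and terminator flanking-sequence composition.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    GenomeInfoDb,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
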